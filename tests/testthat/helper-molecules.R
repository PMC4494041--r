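# Shared builders for test molecules and a cached one-shot validation of the
# whole fixture suite (so the many tests that consult it pay for one backend
# run, not forty).

atoms_df <- function(symbol, x, y, z = 0, charge = 0L, radical = 0L) {
  data.frame(symbol = symbol, x = x, y = y, z = z,
             charge = as.integer(charge), radical = as.integer(radical),
             stringsAsFactors = FALSE)
}

bonds_df <- function(begin, end, order = "single", wedge = "none") {
  n <- length(begin)
  data.frame(begin = as.integer(begin), end = as.integer(end),
             order = rep_len(order, n), wedge = rep_len(wedge, n),
             stringsAsFactors = FALSE)
}

hexagon_coords <- function(r = 1, phase = 90) {
  ang <- (phase - 60 * (0:5)) * pi / 180
  cbind(x = r * cos(ang), y = r * sin(ang))
}

make_ring_record <- function(symbols, order = "aromatic",
                             coords = hexagon_coords()) {
  n <- length(symbols)
  if (nrow(coords) != n) {
    ang <- (90 - 360 / n * (0:(n - 1))) * pi / 180
    coords <- cbind(x = cos(ang), y = sin(ang))
  }
  atoms <- atoms_df(symbols, coords[, 1], coords[, 2])
  bonds <- bonds_df(seq_len(n), c(seq_len(n)[-1], 1L), order = order)
  new_molrec(atoms, bonds)
}

ethanol_record <- function() {
  new_molrec(atoms_df(c("C", "C", "O"), c(0, 1, 2), c(0, 0.5, 0)),
             bonds_df(c(1, 2), c(2, 3)))
}

# -- cached whole-suite validation -------------------------------------------

.suite_cache <- new.env(parent = emptyenv())

validated_suite <- function() {
  if (!is.null(.suite_cache$report)) return(.suite_cache)
  suite <- fixture_suite()
  records <- lapply(seq_along(suite), function(i)
    fixture_record(suite[[i]], i))
  .suite_cache$suite <- suite
  .suite_cache$records <- records
  .suite_cache$report <- build_report(records)
  .suite_cache
}

entry_codes <- function(report, i) {
  sort(unique(vapply(report$entries[[i]]$issues, function(x) x$code,
                     character(1))))
}

# -- random polyprotic molecules for the ionization optimality check ---------

# Attachable acid groups: name, rank, atoms appended to one backbone carbon.
.polyprotic_library <- list(
  sulfo = list(rank = 20L, build = function(ionized) {
    list(atoms = atoms_df(c("S", "O", "O", "O"), c(0, -0.5, 0.5, 0),
                          c(1, 1.8, 1.8, 2),
                          charge = c(0L, 0L, 0L, if (ionized) -1L else 0L)),
         orders = c("single", "double", "double", "single"),
         from = c(0L, 1L, 1L, 1L))  # 0 = backbone carbon, k = k-th new atom
  }),
  carboxyl = list(rank = 70L, build = function(ionized) {
    list(atoms = atoms_df(c("C", "O", "O"), c(0, -0.5, 0.5), c(1, 1.8, 1.8),
                          charge = c(0L, 0L, if (ionized) -1L else 0L)),
         orders = c("single", "double", "single"),
         from = c(0L, 1L, 1L))
  }),
  thiol = list(rank = 180L, build = function(ionized) {
    list(atoms = atoms_df("S", 0, 1, charge = if (ionized) -1L else 0L),
         orders = "single", from = 0L)
  }),
  hydroxyl = list(rank = 240L, build = function(ionized) {
    list(atoms = atoms_df("O", 0, 1, charge = if (ionized) -1L else 0L),
         orders = "single", from = 0L)
  })
)

# A backbone of n CH2/CH3 carbons, carbon i bearing group i.
make_polyprotic <- function(group_names, ionized) {
  n <- length(group_names)
  atoms <- atoms_df("C", seq_len(n) - 1, rep(0, n))
  bonds <- if (n > 1) bonds_df(seq_len(n - 1), seq_len(n - 1) + 1)
           else bonds_df(integer(), integer())
  for (i in seq_len(n)) {
    g <- .polyprotic_library[[group_names[i]]]$build(ionized[i])
    base <- nrow(atoms)
    g$atoms$x <- g$atoms$x + (i - 1)
    atoms <- rbind(atoms, g$atoms)
    for (j in seq_along(g$orders)) {
      from <- if (g$from[j] == 0L) i else base + g$from[j]
      bonds <- rbind(bonds, bonds_df(from, base + j, order = g$orders[j]))
    }
  }
  new_molrec(atoms, bonds)
}

group_rank <- function(name) .polyprotic_library[[name]]$rank
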