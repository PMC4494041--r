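#' Default configuration for validation runs
#'
#' Collects every tunable threshold in one place.  All angles are in degrees,
#' all distances in molfile coordinate units.
#'
#' @param ... named overrides of the defaults listed below.
#'
#' @return A named list with components:
#' \describe{
#'   \item{stereo_min_angle}{two stereo bonds at one atom subtending less
#'     than this angle are flagged `stereo_bond_angle_too_small`
#'     (default 15).}
#'   \item{stereo_opposite_angle}{an up/down wedge pair at one center with
#'     an angle at or above this is "near-opposite" and flagged
#'     `up_and_down_at_center`; a same-type pair *below* it is "adjacent"
#'     and flagged `two_same_wedges_at_center` (default 150).}
#'   \item{angle_rule_severity}{severity of the small-angle finding;
#'     "Warning" by default, may be set to "Error".}
#'   \item{z_3d_threshold}{a record is 3D when any |z| exceeds this
#'     (default 1e-4; drawing programs emit tiny non-zero z).}
#'   \item{collinear_tol}{relative cross-product tolerance below which a
#'     ring-walk turn is degenerate (default 1e-3).}
#'   \item{haworth_edge_ratio}{a hexagon edge at least this many times the
#'     shortest edge counts as "long" for the Haworth heuristic
#'     (default 1.5).}
#'   \item{haworth_axis_angle}{"near-horizontal"/"near-vertical" means
#'     within this many degrees of the axis (default 20).}
#'   \item{dearomatization_cap}{maximum number of hydrogen-placement
#'     assignments enumerated before the check gives up and reports the
#'     ambiguity (default 4096).}
#'   \item{per_fragment_ionization}{compare acid/base ranks within each
#'     fragment separately instead of across the whole record
#'     (default FALSE).}
#'   \item{compare_stereo_layer}{include the stereo layers when comparing
#'     InChI strings during cross-validation (default TRUE).}
#'   \item{standardize}{apply competitive-ionization reprotonation during
#'     `validate_record()`/`build_report()` (default FALSE; validation
#'     only).}
#' }
#' @examples
#' cfg <- chemcheck_options(stereo_min_angle = 10)
#' cfg$stereo_min_angle
#' @export
chemcheck_options <- function(...) {
  defaults <- list(
    stereo_min_angle = 15,
    stereo_opposite_angle = 150,
    angle_rule_severity = "Warning",
    z_3d_threshold = 1e-4,
    collinear_tol = 1e-3,
    haworth_edge_ratio = 1.5,
    haworth_axis_angle = 20,
    dearomatization_cap = 4096,
    per_fragment_ionization = FALSE,
    compare_stereo_layer = TRUE,
    standardize = FALSE
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    stop("unknown chemcheck option(s): ", paste(unknown, collapse = ", "))
  }
  defaults[names(overrides)] <- overrides
  defaults
}
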