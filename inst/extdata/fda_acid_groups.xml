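<?xml version="1.0" encoding="UTF-8"?>
<!--
  Ranked acid/base pairs for competitive-ionization checking, following the
  FDA Substance Registry System recommendation that the most acidic proton
  of a partially ionized structure be removed first.  Smaller rank = more
  acidic.  Each entry carries the SMARTS of the protonated (acid) and
  deprotonated (conjugate base) forms plus atom-mapped SMIRKS for the two
  proton moves.

  Typographical repairs relative to the published table:
    - amide acid "C(=O)[NH2" completed to "C(=O)[NH2]" (unbalanced bracket);
    - "H at sp3 carbon" conjugate base "[CX3-]" read as "[CX4;-]" (the
      printed form duplicates the sp2 row's base);
    - imidazole acid "c1cnc[n]1" tightened to "c1cnc[n;H]1" (as printed it
      carries no H requirement and would also match the conjugate base);
    - spurious spaces inside printed SMARTS removed.
-->
<acidgroups>
  <acidgroup name="OSO3H" rank="10"
    acid="OS(=O)(=O)[O;H]" base="OS(=O)(=O)[O-]"
    acid2base="OS(=O)(=O)[O;H:1]&gt;&gt;OS(=O)(=O)[O-:1]"
    base2acid="OS(=O)(=O)[O-:1]&gt;&gt;OS(=O)(=O)[O;H:1]"/>
  <acidgroup name="SO3H" rank="20"
    acid="[!O]S(=O)(=O)[O;H]" base="[!O]S(=O)(=O)[O-]"
    acid2base="[!O]S(=O)(=O)[O;H:1]&gt;&gt;[!O]S(=O)(=O)[O-:1]"
    base2acid="[!O]S(=O)(=O)[O-:1]&gt;&gt;[!O]S(=O)(=O)[O;H:1]"/>
  <acidgroup name="OSO2H" rank="30"
    acid="O[S;D3](=O)[O;H]" base="O[S;D3](=O)[O-]"
    acid2base="O[S;D3](=O)[O;H:1]&gt;&gt;O[S;D3](=O)[O-:1]"
    base2acid="O[S;D3](=O)[O-:1]&gt;&gt;O[S;D3](=O)[O;H:1]"/>
  <acidgroup name="SO2H" rank="40"
    acid="[!O][S;D3](=O)[O;H]" base="[!O][S;D3](=O)[O-]"
    acid2base="[!O][S;D3](=O)[O;H:1]&gt;&gt;[!O][S;D3](=O)[O-:1]"
    base2acid="[!O][S;D3](=O)[O-:1]&gt;&gt;[!O][S;D3](=O)[O;H:1]"/>
  <acidgroup name="OPO3H2" rank="50"
    acid="OP(=O)([O;H])[O;H]" base="OP(=O)([O;H])[O-]"
    acid2base="OP(=O)([O;H])[O;H:1]&gt;&gt;OP(=O)([O;H])[O-:1]"
    base2acid="OP(=O)([O;H])[O-:1]&gt;&gt;OP(=O)([O;H])[O;H:1]"/>
  <acidgroup name="PO3H2" rank="60"
    acid="[!O]P(=O)([O;H])[O;H]" base="[!O]P(=O)([O;H])[O-]"
    acid2base="[!O]P(=O)([O;H])[O;H:1]&gt;&gt;[!O]P(=O)([O;H])[O-:1]"
    base2acid="[!O]P(=O)([O;H])[O-:1]&gt;&gt;[!O]P(=O)([O;H])[O;H:1]"/>
  <acidgroup name="CO2H" rank="70"
    acid="C(=O)[O;H]" base="C(=O)[O-]"
    acid2base="C(=O)[O;H:1]&gt;&gt;C(=O)[O-:1]"
    base2acid="C(=O)[O-:1]&gt;&gt;C(=O)[O;H:1]"/>
  <acidgroup name="Arom-SH" rank="80"
    acid="c[S;H]" base="c[S-]"
    acid2base="c[S;H:1]&gt;&gt;c[S-:1]"
    base2acid="c[S-:1]&gt;&gt;c[S;H:1]"/>
  <acidgroup name="OPO3H-" rank="90"
    acid="OP(=O)([O;H])[O-]" base="OP(=O)([O-])[O-]"
    acid2base="OP(=O)([O;H:1])[O-]&gt;&gt;OP(=O)([O-:1])[O-]"
    base2acid="OP(=O)([O-:1])[O-]&gt;&gt;OP(=O)([O;H:1])[O-]"/>
  <acidgroup name="PO3H" rank="100"
    acid="[!O]P(=O)([O;H])[O-]" base="[!O]P(=O)([O-])[O-]"
    acid2base="[!O]P(=O)([O;H:1])[O-]&gt;&gt;[!O]P(=O)([O-:1])[O-]"
    base2acid="[!O]P(=O)([O-:1])[O-]&gt;&gt;[!O]P(=O)([O;H:1])[O-]"/>
  <acidgroup name="Phthalimide" rank="110"
    acid="O=C2c1ccccc1C(=O)[N;H]2" base="O=C2c1ccccc1C(=O)[N-]2"
    acid2base="O=C2c1ccccc1C(=O)[N;H:1]2&gt;&gt;O=C2c1ccccc1C(=O)[N-:1]2"
    base2acid="O=C2c1ccccc1C(=O)[N-:1]2&gt;&gt;O=C2c1ccccc1C(=O)[N;H:1]2"/>
  <acidgroup name="CO3H" rank="120"
    acid="C(=O)O[O;H]" base="C(=O)O[O-]"
    acid2base="C(=O)O[O;H:1]&gt;&gt;C(=O)O[O-:1]"
    base2acid="C(=O)O[O-:1]&gt;&gt;C(=O)O[O;H:1]"/>
  <acidgroup name="alpha-C-to-NO2" rank="130"
    acid="O=N(O)[C;H]" base="O=N(O)[C-]"
    acid2base="O=N(O)[C;H:1]&gt;&gt;O=N(O)[C-:1]"
    base2acid="O=N(O)[C-:1]&gt;&gt;O=N(O)[C;H:1]"/>
  <acidgroup name="SO2NH2" rank="140"
    acid="S(=O)(=O)[NH2]" base="S(=O)(=O)[NH-]"
    acid2base="S(=O)(=O)[NH2:1]&gt;&gt;S(=O)(=O)[NH-:1]"
    base2acid="S(=O)(=O)[NH-:1]&gt;&gt;S(=O)(=O)[NH2:1]"/>
  <acidgroup name="OB(OH)2" rank="150"
    acid="OB([OH])[OH]" base="OB([OH])[O-]"
    acid2base="OB([OH])[OH:1]&gt;&gt;OB([OH])[O-:1]"
    base2acid="OB([OH])[O-:1]&gt;&gt;OB([OH])[OH:1]"/>
  <acidgroup name="B(OH)2" rank="160"
    acid="[!O]B([OH])[OH]" base="[!O]B([OH])[O-]"
    acid2base="[!O]B([OH])[OH:1]&gt;&gt;[!O]B([OH])[O-:1]"
    base2acid="[!O]B([OH])[O-:1]&gt;&gt;[!O]B([OH])[OH:1]"/>
  <acidgroup name="Arom-OH" rank="170"
    acid="c[OH]" base="c[O-]"
    acid2base="c[OH:1]&gt;&gt;c[O-:1]"
    base2acid="c[O-:1]&gt;&gt;c[OH:1]"/>
  <acidgroup name="SH-aliphatic" rank="180"
    acid="C[SH]" base="C[S-]"
    acid2base="C[SH:1]&gt;&gt;C[S-:1]"
    base2acid="C[S-:1]&gt;&gt;C[SH:1]"/>
  <acidgroup name="OBO2H" rank="190"
    acid="OB([OH])[O-]" base="OB([O-])[O-]"
    acid2base="OB([OH:1])[O-]&gt;&gt;OB([O-:1])[O-]"
    base2acid="OB([O-:1])[O-]&gt;&gt;OB([OH:1])[O-]"/>
  <acidgroup name="BO2H" rank="200"
    acid="[!O]B([OH])[O-]" base="[!O]B([O-])[O-]"
    acid2base="[!O]B([OH:1])[O-]&gt;&gt;[!O]B([O-:1])[O-]"
    base2acid="[!O]B([O-:1])[O-]&gt;&gt;[!O]B([OH:1])[O-]"/>
  <acidgroup name="Cyclopentadiene" rank="210"
    acid="[CH2]1C=CC=C1" base="[C-]1C=CC=C1"
    acid2base="[CH2:1]1C=CC=C1&gt;&gt;[C-:1]1C=CC=C1"
    base2acid="[C-:1]1C=CC=C1&gt;&gt;[CH2:1]1C=CC=C1"/>
  <acidgroup name="Amide" rank="220"
    acid="C(=O)[NH2]" base="C(=O)[N;H;-]"
    acid2base="C(=O)[NH2:1]&gt;&gt;C(=O)[N;H;-:1]"
    base2acid="C(=O)[N;H;-:1]&gt;&gt;C(=O)[NH2:1]"/>
  <acidgroup name="Imidazole" rank="230"
    acid="c1cnc[n;H]1" base="c1cnc[n-]1"
    acid2base="c1cnc[n;H:1]1&gt;&gt;c1cnc[n-:1]1"
    base2acid="c1cnc[n-:1]1&gt;&gt;c1cnc[n;H:1]1"/>
  <acidgroup name="Aliphatic-OH" rank="240"
    acid="[CX4][OH]" base="[CX4][O-]"
    acid2base="[CX4][OH:1]&gt;&gt;[CX4][O-:1]"
    base2acid="[CX4][O-:1]&gt;&gt;[CX4][OH:1]"/>
  <acidgroup name="alpha-C-to-carboxyl" rank="250"
    acid="O=C[CH]" base="O=C[C-]"
    acid2base="O=C[CH:1]&gt;&gt;O=C[C-:1]"
    base2acid="O=C[C-:1]&gt;&gt;O=C[CH:1]"/>
  <acidgroup name="alpha-C-to-acetyl" rank="260"
    acid="OC(=O)[CH]" base="OC(=O)[C-]"
    acid2base="OC(=O)[CH:1]&gt;&gt;OC(=O)[C-:1]"
    base2acid="OC(=O)[C-:1]&gt;&gt;OC(=O)[CH:1]"/>
  <acidgroup name="H-at-sp-carbon" rank="270"
    acid="C#[CH]" base="C#[C-]"
    acid2base="C#[CH:1]&gt;&gt;C#[C-:1]"
    base2acid="C#[C-:1]&gt;&gt;C#[CH:1]"/>
  <acidgroup name="alpha-C-of-sulfone" rank="280"
    acid="CS(=O)(=O)C[CH]" base="CS(=O)(=O)C[C-]"
    acid2base="CS(=O)(=O)C[CH:1]&gt;&gt;CS(=O)(=O)C[C-:1]"
    base2acid="CS(=O)(=O)C[C-:1]&gt;&gt;CS(=O)(=O)C[CH:1]"/>
  <acidgroup name="alpha-C-of-sulfoxide" rank="290"
    acid="C[S;D3](=O)C[CH]" base="C[S;D3](=O)C[C-]"
    acid2base="C[S;D3](=O)C[CH:1]&gt;&gt;C[S;D3](=O)C[C-:1]"
    base2acid="C[S;D3](=O)C[C-:1]&gt;&gt;C[S;D3](=O)C[CH:1]"/>
  <acidgroup name="Amine" rank="300"
    acid="[CX4][NH2]" base="[CX4][N;H;-]"
    acid2base="[CX4][NH2:1]&gt;&gt;[CX4][N;H;-:1]"
    base2acid="[CX4][N;H;-:1]&gt;&gt;[CX4][NH2:1]"/>
  <acidgroup name="Benzyl" rank="310"
    acid="c[C;D4;H]" base="c[C;D3;-]"
    acid2base="c[C;D4;H:1]&gt;&gt;c[C;D3;-:1]"
    base2acid="c[C;D3;-:1]&gt;&gt;c[C;D4;H:1]"/>
  <acidgroup name="H-at-sp2-carbon" rank="320"
    acid="[CX3;H]" base="[CX3;-]"
    acid2base="[CX3;H:1]&gt;&gt;[CX3;-:1]"
    base2acid="[CX3;-:1]&gt;&gt;[CX3;H:1]"/>
  <acidgroup name="H-at-sp3-carbon" rank="330"
    acid="[CX4;H]" base="[CX4;-]"
    acid2base="[CX4;H:1]&gt;&gt;[CX4;-:1]"
    base2acid="[CX4;-:1]&gt;&gt;[CX4;H:1]"/>
</acidgroups>
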