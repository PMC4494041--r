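<?xml version="1.0" encoding="UTF-8"?>
<!--
  Default platform-wide dictionary rules.

  The exact SMARTS behind the platform's default dictionary are not public;
  the patterns below are best-effort reconstructions from the rule names
  (enol, non-1H-tetrazole, N=C-OH, azide written N#N=N, small fragments,
  free carbon monoxide, adjacent like charges, metal bonds).  Edit freely:
  the engine expands {M}/{NM}/... abbreviations from abbreviations.yaml at
  load time.

  Notes on individual patterns:
  - fragment_small_molecule uses D0 (no explicit connections) so it matches
    the usual all-implicit-hydrogen depictions of methane/ammonia/water and
    any lone sulfur or boron atom.
  - non_1h_tetrazole matches a tetrazole whose ring N-H is NOT adjacent to
    the ring carbon (the 2H tautomer); the 1H form is the accepted one.
  - azide: the correct depiction is charge-separated N=[N+]=[N-]; the rule
    flags the hypervalent as-drawn form N#N=N.
  - free_carbon_monoxide: both C#O as drawn and [C-]#[O+] have one
    single-connection carbon triple-bonded to a single-connection oxygen.
-->
<rules origin="default">
  <Warning name="fragment_small_molecule"
           message="Small-molecule fragment (methane, ammonia, water, S, B)"
           description="A component of the record is methane, ammonia, water or a lone sulfur/boron atom; usually a leftover of incomplete salt/solvate cleanup.">
    <or>
      <test name="SMARTStest" param="[CD0;H4]"/>
      <test name="SMARTStest" param="[ND0;H3]"/>
      <test name="SMARTStest" param="[OD0;H2]"/>
      <test name="SMARTStest" param="[SD0]"/>
      <test name="SMARTStest" param="[BD0]"/>
    </or>
  </Warning>
  <Information name="adjacent_like_charges"
               message="Adjacent atoms with like charges"
               description="Two bonded atoms carry formal charges of the same sign.">
    <or>
      <test name="SMARTStest" param="[+,+2,+3]~[+,+2,+3]"/>
      <test name="SMARTStest" param="[-,-2,-3]~[-,-2,-3]"/>
    </or>
  </Information>
  <Information name="metal_nonmetal_bond"
               message="Covalent bond connecting a metal to a non-metal"
               description="Metal-to-non-metal bonds are frequently intended to be ionic; review the depiction.">
    <test name="SMARTStest" param="{M}~{NM}"/>
  </Information>
  <Information name="metal_nitrogen_bond"
               message="Contains metal-nitrogen bond"
               description="Covalent bond between a metal and nitrogen.">
    <test name="SMARTStest" param="{M}~[#7]"/>
  </Information>
  <Information name="metal_oxygen_bond"
               message="Contains metal-oxygen bond"
               description="Covalent bond between a metal and oxygen.">
    <test name="SMARTStest" param="{M}~[#8]"/>
  </Information>
  <Information name="contains_enol"
               message="Contains enol function"
               description="A hydroxyl on an aliphatic C=C carbon; usually the unstable tautomer of a carbonyl compound.">
    <test name="SMARTStest" param="[CX3]=[CX3][OX2;H]"/>
  </Information>
  <Information name="non_1h_tetrazole"
               message="Contains non-1H-tetrazole"
               description="Tetrazole drawn with the ring hydrogen away from the carbon-adjacent nitrogen (2H tautomer).">
    <test name="SMARTStest" param="c1n[nH]nn1"/>
  </Information>
  <Information name="iminol_tautomer"
               message="Contains N=C-OH group"
               description="Iminol (amide tautomer) group as drawn.">
    <test name="SMARTStest" param="[NX2]=[CX3][OX2;H]"/>
  </Information>
  <Information name="azide_drawn_hypervalent"
               message="Azide written as N#N=N"
               description="Azide drawn with a pentavalent nitrogen instead of the charge-separated form N=[N+]=[N-].">
    <test name="SMARTStest" param="[#7]#[#7]=[#7]"/>
  </Information>
  <Warning name="free_carbon_monoxide"
           message="Free carbon monoxide"
           description="A carbon monoxide fragment; usually an artifact of metal-complex cleanup.">
    <test name="SMARTStest" param="[#6D1]#[#8D1]"/>
  </Warning>
</rules>
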