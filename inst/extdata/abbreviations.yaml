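NM:
  description: Non-metals less carbon
  elements:
  - He
  - B
  - 'N'
  - O
  - F
  - Ne
  - Si
  - P
  - S
  - Cl
  - Ar
  - Ge
  - As
  - Se
  - Br
  - Kr
  - Sb
  - Te
  - I
  - Xe
  - Po
  - At
M:
  description: 'Metals (everything else: not a non-metal, not C or H)'
  elements:
  - Li
  - Be
  - Na
  - Mg
  - Al
  - K
  - Ca
  - Sc
  - Ti
  - V
  - Cr
  - Mn
  - Fe
  - Co
  - Ni
  - Cu
  - Zn
  - Ga
  - Rb
  - Sr
  - 'Y'
  - Zr
  - Nb
  - Mo
  - Tc
  - Ru
  - Rh
  - Pd
  - Ag
  - Cd
  - In
  - Sn
  - Cs
  - Ba
  - La
  - Ce
  - Pr
  - Nd
  - Pm
  - Sm
  - Eu
  - Gd
  - Tb
  - Dy
  - Ho
  - Er
  - Tm
  - Yb
  - Lu
  - Hf
  - Ta
  - W
  - Re
  - Os
  - Ir
  - Pt
  - Au
  - Hg
  - Tl
  - Pb
  - Bi
  - Rn
  - Fr
  - Ra
  - Ac
  - Th
  - Pa
  - U
  - Np
  - Pu
  - Am
  - Cm
  - Bk
  - Cf
  - Es
  - Fm
  - Md
  - 'No'
  - Lr
Pn:
  description: Pnictogens
  elements:
  - P
  - As
  - Sb
Hal:
  description: Halogens
  elements:
  - F
  - Cl
  - Br
  - I
M_V6:
  description: Metals with maximum valency 6
  elements:
  - Cr
  - Mo
  - W
  - Mn
  - Pt
TM:
  description: Transition metals (d-block)
  elements:
  - Sc
  - Ti
  - V
  - Cr
  - Mn
  - Fe
  - Co
  - Ni
  - Cu
  - Zn
  - 'Y'
  - Zr
  - Nb
  - Mo
  - Tc
  - Ru
  - Rh
  - Pd
  - Ag
  - Cd
  - La
  - Hf
  - Ta
  - W
  - Re
  - Os
  - Ir
  - Pt
  - Au
  - Hg
  - Ac
TM^Hg:
  description: Transition metals apart from mercury
  elements:
  - Sc
  - Ti
  - V
  - Cr
  - Mn
  - Fe
  - Co
  - Ni
  - Cu
  - Zn
  - 'Y'
  - Zr
  - Nb
  - Mo
  - Tc
  - Ru
  - Rh
  - Pd
  - Ag
  - Cd
  - La
  - Hf
  - Ta
  - W
  - Re
  - Os
  - Ir
  - Pt
  - Au
  - Ac
M_+1:
  description: Metals with a charge of +1
  elements:
  - Li
  - Be
  - Na
  - Mg
  - Al
  - K
  - Ca
  - Sc
  - Ti
  - V
  - Cr
  - Mn
  - Fe
  - Co
  - Ni
  - Cu
  - Zn
  - Ga
  - Rb
  - Sr
  - 'Y'
  - Zr
  - Nb
  - Mo
  - Tc
  - Ru
  - Rh
  - Pd
  - Ag
  - Cd
  - In
  - Sn
  - Cs
  - Ba
  - La
  - Ce
  - Pr
  - Nd
  - Pm
  - Sm
  - Eu
  - Gd
  - Tb
  - Dy
  - Ho
  - Er
  - Tm
  - Yb
  - Lu
  - Hf
  - Ta
  - W
  - Re
  - Os
  - Ir
  - Pt
  - Au
  - Hg
  - Tl
  - Pb
  - Bi
  - Rn
  - Fr
  - Ra
  - Ac
  - Th
  - Pa
  - U
  - Np
  - Pu
  - Am
  - Cm
  - Bk
  - Cf
  - Es
  - Fm
  - Md
  - 'No'
  - Lr
  charge: 1
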