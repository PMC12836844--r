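# Generic fast-growing boreal deciduous species (hybrid-poplar-like).
# Editable configuration; annual foliage turnover is handled by the
# phenology scheme, so the continuous litterfall rates are zero.
name: generic_deciduous
Tmin_g: 1.0
Topt_g: 18.0
Tmax_g: 32.0
kF: 1.0
CoeffCond: 0.08
MaxCond: 0.014
LAIgcx: 3.0
SWconst: 0.6
SWpower: 7.0
fN0: 0.6
fNn: 1.0
MaxAge: 120
rAge: 0.95
nAge: 4.0
alphaCx: 0.06
"Y": 0.47
k: 0.4
pFS2: 1.2
pFS20: 0.45
aS: 0.075
nS: 2.5
pRx: 0.80
pRn: 0.35
m0: 0.0
gammaF0: 0.12     # month-1, in-season foliage turnover while in leaf
gammaFx: 0.12
tgammaF: 24
gammaR: 0.015
gammaN: 0.02
wSx1000: 140
thinPower: 1.5
SLA0: 18.0
SLA1: 12.0
tSLA: 4.0
fCalpha700: 1.4
MaxIntcptn: 0.15
LAImaxIntcptn: 3.0
deciduous: true
leaf_on_Tthresh: 5.0  # degC mean monthly temperature for leaf flush
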