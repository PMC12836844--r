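# Lodgepole pine (Pinus contorta) 3-PG parameter set.
# Editable configuration based on published western-pine parameterisations.
name: lodgepole_pine
Tmin_g: -1.0
Topt_g: 16.0
Tmax_g: 30.0
kF: 1.0
CoeffCond: 0.05
MaxCond: 0.02
LAIgcx: 3.0
SWconst: 0.6
SWpower: 7.0
fN0: 0.6
fNn: 1.0
MaxAge: 220
rAge: 0.95
nAge: 4.0
alphaCx: 0.055
"Y": 0.47
k: 0.5
pFS2: 1.0
pFS20: 0.30
aS: 0.090
nS: 2.45
pRx: 0.80
pRn: 0.25
m0: 0.0
gammaF0: 0.001
gammaFx: 0.018
tgammaF: 24
gammaR: 0.015
gammaN: 0.010
wSx1000: 280
thinPower: 1.5
SLA0: 5.0
SLA1: 3.5
tSLA: 4.0
fCalpha700: 1.4
MaxIntcptn: 0.15
LAImaxIntcptn: 3.0
deciduous: false
leaf_on_Tthresh: -99.0
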