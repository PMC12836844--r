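# Black spruce (Picea mariana) 3-PG parameter set.
# Assembled from published parameterisations of similar boreal spruces
# (white, Norway, Sitka); editable configuration, not a calibrated contract.
name: black_spruce
Tmin_g: -2.0      # degC, growth temperature minimum
Topt_g: 14.0      # degC, growth temperature optimum
Tmax_g: 28.0      # degC, growth temperature maximum
kF: 1.0           # frost sensitivity (1 = full shut-down on frost days)
CoeffCond: 0.05   # mbar-1, stomatal response to VPD
MaxCond: 0.02     # m s-1, maximum canopy conductance
LAIgcx: 3.0       # LAI at which canopy conductance saturates
SWconst: 0.6      # soil-water response constant (sandy loam default)
SWpower: 7.0      # soil-water response power
fN0: 0.6          # fNutr at fertility rating 0
fNn: 1.0          # fertility response power
MaxAge: 250       # yr, maximum stand age for the age modifier
rAge: 0.95        # relative age at fAge = 0.5
nAge: 4.0         # age modifier power
alphaCx: 0.050    # mol C mol PAR-1, maximum canopy quantum efficiency
"Y": 0.47           # NPP/GPP ratio
k: 0.5            # light extinction coefficient
pFS2: 1.0         # foliage:stem partitioning at DBH 2 cm
pFS20: 0.30       # foliage:stem partitioning at DBH 20 cm
aS: 0.095         # stem allometry multiplier (kg tree-1 = aS * DBH^nS)
nS: 2.4           # stem allometry power
pRx: 0.80         # maximum root allocation fraction
pRn: 0.25         # minimum root allocation fraction
m0: 0.0           # fertility effect on root allocation at FR = 0
gammaF0: 0.001    # month-1, litterfall rate at age 0
gammaFx: 0.015    # month-1, mature litterfall rate
tgammaF: 24       # months to litterfall midpoint
gammaR: 0.015     # month-1, root turnover
gammaN: 0.010     # yr-1, background stem mortality
wSx1000: 300      # kg tree-1, max mean stem mass at 1000 trees ha-1
thinPower: 1.5    # self-thinning power
SLA0: 6.0         # m2 kg-1, specific leaf area of young foliage
SLA1: 4.0         # m2 kg-1, specific leaf area of mature foliage
tSLA: 5.0         # yr, SLA age midpoint
fCalpha700: 1.4   # quantum-efficiency ratio at 700 ppm CO2
MaxIntcptn: 0.15  # maximum rainfall interception fraction
LAImaxIntcptn: 3.0 # LAI at which interception saturates
deciduous: false
leaf_on_Tthresh: -99.0  # unused for evergreens
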