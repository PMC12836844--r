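## Package-wide vocabularies and fixed tables (loaded first).

DAYS_IN_MONTH <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)

LANDCOVER_LEVELS <- c("coniferous_forest", "deciduous_forest", "shrubland",
                      "herbs", "water", "rock_rubble", "snow_ice", "bryoid")

NONVEGETATED_CLASSES <- c("water", "rock_rubble", "snow_ice", "bryoid")

CLIMATE_SCENARIOS <- c("CS1", "CS2", "CS3")
CLIMATE_PERIODS <- c("2021-2040", "2041-2060", "2061-2080")
PLANTING_RULES <- c("SM1", "SM2", "SM3")

`%||%` <- function(a, b) if (is.null(a)) b else a
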