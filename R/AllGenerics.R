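#' Accessor generics
#'
#' Small accessor family for the landscape and result containers, so user code
#' never touches slots directly.
#'
#' @param x An object.
#' @param ... Passed to methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("demLayer", function(x, ...) standardGeneric("demLayer"))
#' @rdname accessors
#' @export
setGeneric("socLayer", function(x, ...) standardGeneric("socLayer"))
#' @rdname accessors
#' @export
setGeneric("landcoverLayer", function(x, ...) standardGeneric("landcoverLayer"))
#' @rdname accessors
#' @export
setGeneric("forestHistory", function(x, ...) standardGeneric("forestHistory"))
#' @rdname accessors
#' @export
setGeneric("climateNormals", function(x, ...) standardGeneric("climateNormals"))
#' @rdname accessors
#' @export
setGeneric("fertilityRating", function(x, ...) standardGeneric("fertilityRating"))
#' @rdname accessors
#' @export
setGeneric("maswLayer", function(x, ...) standardGeneric("maswLayer"))
#' @rdname accessors
#' @export
setGeneric("eligibleMask", function(x, ...) standardGeneric("eligibleMask"))
#' @rdname accessors
#' @export
setGeneric("normalizedWetnessLayer", function(x, ...) standardGeneric("normalizedWetnessLayer"))
#' @rdname accessors
#' @export
setGeneric("assignmentLayer", function(x, ...) standardGeneric("assignmentLayer"))
#' @rdname accessors
#' @export
setGeneric("agbByYear", function(x, ...) standardGeneric("agbByYear"))
#' @rdname accessors
#' @export
setGeneric("finalAGB", function(x, ...) standardGeneric("finalAGB"))
#' @rdname accessors
#' @export
setGeneric("modifierTrace", function(x, ...) standardGeneric("modifierTrace"))
#' @rdname accessors
#' @export
setGeneric("plantedCells", function(x, ...) standardGeneric("plantedCells"))

#' @rdname accessors
#' @param x The container object.
#' @export
setMethod("demLayer", "LandscapeBundle", function(x, ...) x@dem)
#' @rdname accessors
#' @export
setMethod("socLayer", "LandscapeBundle", function(x, ...) x@soc)
#' @rdname accessors
#' @param codes Logical; return integer codes instead of class names.
#' @export
setMethod("landcoverLayer", "LandscapeBundle", function(x, codes = FALSE, ...) {
  if (codes) return(x@landcover)
  m <- matrix(LANDCOVER_LEVELS[x@landcover], nrow(x@landcover))
  m
})
#' @rdname accessors
#' @export
setMethod("forestHistory", "LandscapeBundle", function(x, ...) x@forest_history)
#' @rdname accessors
#' @param scenario,period Select one climate set; both NULL returns the list.
#' @export
setMethod("climateNormals", "LandscapeBundle",
  function(x, scenario = NULL, period = NULL, ...) {
    if (is.null(scenario) && is.null(period)) return(x@climate)
    key <- paste(scenario, period, sep = "|")
    if (!key %in% names(x@climate))
      stop("no climate normals for ", key, call. = FALSE)
    x@climate[[key]]
  })
#' @rdname accessors
#' @export
setMethod("fertilityRating", "SiteGrid", function(x, ...) x@fr)
#' @rdname accessors
#' @export
setMethod("maswLayer", "SiteGrid", function(x, ...) x@masw)
#' @rdname accessors
#' @export
setMethod("eligibleMask", "SiteGrid", function(x, ...) x@eligible)
#' @rdname accessors
#' @export
setMethod("normalizedWetnessLayer", "SiteGrid", function(x, ...) x@nw)
#' @rdname accessors
#' @export
setMethod("assignmentLayer", "PlantingMap", function(x, ...) x@assignment)
#' @rdname accessors
#' @export
setMethod("agbByYear", "ScenarioResult", function(x, ...) {
  m <- x@agb
  dimnames(m) <- list(cell = x@cells, year = x@years)
  m
})
#' @rdname accessors
#' @export
setMethod("finalAGB", "ScenarioResult", function(x, ...) {
  if (!length(x@cells)) return(numeric(0))
  setNames(x@agb[, ncol(x@agb)], x@cells)
})
#' @rdname accessors
#' @export
setMethod("modifierTrace", "ScenarioResult", function(x, ...) x@trace)
#' @rdname accessors
#' @export
setMethod("plantedCells", "ScenarioResult", function(x, ...) x@cells)
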