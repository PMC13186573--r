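#' Accessors for PAApipe classes
#'
#' Small accessor generics for the package's S4 classes; use these rather
#' than reaching into slots.
#'
#' @param x an object of the documented class.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("archSignature", function(x) standardGeneric("archSignature"))
#' @rdname accessors
#' @export
setGeneric("archCoverage", function(x) standardGeneric("archCoverage"))
#' @rdname accessors
#' @export
setGeneric("archTiles", function(x) standardGeneric("archTiles"))
#' @rdname accessors
#' @export
setGeneric("proteinId", function(x) standardGeneric("proteinId"))
#' @rdname accessors
#' @export
setGeneric("motifId", function(x) standardGeneric("motifId"))
#' @rdname accessors
#' @export
setGeneric("motifWidth", function(x) standardGeneric("motifWidth"))
#' @rdname accessors
#' @export
setGeneric("motifPPM", function(x) standardGeneric("motifPPM"))
#' @rdname accessors
#' @export
setGeneric("motifBackground", function(x) standardGeneric("motifBackground"))
#' @rdname accessors
#' @export
setGeneric("contextWindow", function(x) standardGeneric("contextWindow"))
#' @rdname accessors
#' @export
setGeneric("contextAnchor", function(x) standardGeneric("contextAnchor"))
#' @rdname accessors
#' @export
setGeneric("configurationOf", function(x) standardGeneric("configurationOf"))
#' @rdname accessors
#' @export
setGeneric("regulatorState", function(x) standardGeneric("regulatorState"))
#' @rdname accessors
#' @export
setGeneric("pacoM2", function(x) standardGeneric("pacoM2"))
#' @rdname accessors
#' @export
setGeneric("pacoPvalue", function(x) standardGeneric("pacoPvalue"))
#' @rdname accessors
#' @export
setGeneric("pacoResiduals", function(x) standardGeneric("pacoResiduals"))
#' @rdname accessors
#' @export
setGeneric("bandOf", function(x) standardGeneric("bandOf"))
#' @rdname accessors
#' @export
setGeneric("bandThresholds", function(x) standardGeneric("bandThresholds"))
#' @rdname accessors
#' @export
setGeneric("extremeOutliers", function(x) standardGeneric("extremeOutliers"))

#' @rdname accessors
setMethod("archSignature", "ProteinArchitecture", function(x) x@signature)
#' @rdname accessors
setMethod("archCoverage", "ProteinArchitecture", function(x) x@coverage)
#' @rdname accessors
setMethod("archTiles", "ProteinArchitecture", function(x) x@tiles)
#' @rdname accessors
setMethod("proteinId", "ProteinArchitecture", function(x) x@protein_id)
#' @rdname accessors
setMethod("motifId", "MotifMatrix", function(x) x@motif_id)
#' @rdname accessors
setMethod("motifWidth", "MotifMatrix", function(x) nrow(x@ppm))
#' @rdname accessors
setMethod("motifPPM", "MotifMatrix", function(x) x@ppm)
#' @rdname accessors
setMethod("motifBackground", "MotifMatrix", function(x) x@background)
#' @rdname accessors
setMethod("contextWindow", "GenomicContext", function(x) x@window)
#' @rdname accessors
setMethod("contextAnchor", "GenomicContext", function(x) x@anchor)
#' @rdname accessors
setMethod("configurationOf", "PathwayConfiguration", function(x) x@configuration)
#' @rdname accessors
setMethod("regulatorState", "PathwayConfiguration", function(x) x@regulator_state)
#' @rdname accessors
setMethod("pacoM2", "PACoResult", function(x) x@m2)
#' @rdname accessors
setMethod("pacoPvalue", "PACoResult", function(x) x@p_value)
#' @rdname accessors
setMethod("pacoResiduals", "PACoResult", function(x) x@residuals)
#' @rdname accessors
setMethod("bandOf", "ResidualBands", function(x) x@band)
#' @rdname accessors
setMethod("bandThresholds", "ResidualBands", function(x) x@thresholds)
#' @rdname accessors
setMethod("extremeOutliers", "ResidualBands", function(x) x@extreme_outlier)

setMethod("show", "ProteinArchitecture", function(object) {
  cat("ProteinArchitecture for", object@protein_id,
      sprintf("(%d aa)\n", object@protein_length))
  cat("  signature:", if (nzchar(object@signature)) object@signature else "<empty>", "\n")
  cat(sprintf("  %d tile(s), coverage %.3f\n", nrow(object@tiles), object@coverage))
})

setMethod("show", "MotifMatrix", function(object) {
  cat(sprintf("MotifMatrix %s: width %d, nsites %d\n",
              object@motif_id, nrow(object@ppm), object@nsites))
})

setMethod("show", "GenomicContext", function(object) {
  cat(sprintf("GenomicContext %s/%s around %s: %d gene(s), W = %d\n",
              object@genome_id, object@replicon_id, object@anchor,
              nrow(object@window), object@W))
  if ("role" %in% names(object@window)) {
    r <- object@window$role
    cat("  roles:", paste(sort(unique(r[!is.na(r)])), collapse = ", "), "\n")
  }
})

setMethod("show", "PathwayConfiguration", function(object) {
  cat(sprintf("PathwayConfiguration: %s, regulator %s, PaaY %s%s\n",
              object@configuration, object@regulator_state,
              if (object@paaY_present) "present" else "absent",
              if (object@ambiguous) " (ambiguous paralogue call)" else ""))
})

setMethod("show", "PACoResult", function(object) {
  cat(sprintf("PACoResult: m2 = %.6g, p = %.4g (%d permutations, seed %d)\n",
              object@m2, object@p_value, object@nperm, object@seed))
  cat(sprintf("  %d link(s); residual range [%.4g, %.4g]\n",
              length(object@residuals),
              if (length(object@residuals)) min(object@residuals) else NA,
              if (length(object@residuals)) max(object@residuals) else NA))
})

setMethod("show", "ResidualBands", function(object) {
  th <- object@thresholds
  cat(sprintf("ResidualBands: q1 = %.4g, q3 = %.4g, p90 = %.4g, extreme = %.4g\n",
              th["q1"], th["q3"], th["p90"], th["extreme"]))
  print(table(object@band))
  cat(sprintf("  extreme outliers: %d\n", sum(object@extreme_outlier)))
})
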