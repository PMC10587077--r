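# Accessor generics and show methods.

#' @name accessors
#' @title Accessors for bmilfp classes
#' @description Slot accessors for the package's S4 containers. Use these
#'   rather than \code{@} access.
#' @param object an object of the documented class.
#' @return the corresponding slot value.
NULL

#' @rdname accessors
#' @export
setGeneric("lfp", function(object) standardGeneric("lfp"))
#' @rdname accessors
#' @export
setMethod("lfp", "SessionRecord", function(object) object@lfp)

#' @rdname accessors
#' @export
setGeneric("channelMap", function(object) standardGeneric("channelMap"))
#' @rdname accessors
#' @export
setMethod("channelMap", "SessionRecord", function(object) object@channelMap)
#' @rdname accessors
#' @export
setMethod("channelMap", "EpochSet", function(object) object@channelMap)

#' @rdname accessors
#' @export
setGeneric("trials", function(object) standardGeneric("trials"))
#' @rdname accessors
#' @export
setMethod("trials", "SessionRecord", function(object) object@trials)

#' @rdname accessors
#' @export
setGeneric("taskType", function(object) standardGeneric("taskType"))
#' @rdname accessors
#' @export
setMethod("taskType", "SessionRecord", function(object) object@taskType)

#' @rdname accessors
#' @export
setGeneric("dayIndex", function(object) standardGeneric("dayIndex"))
#' @rdname accessors
#' @export
setMethod("dayIndex", "SessionRecord", function(object) object@dayIndex)

#' @rdname accessors
#' @export
setGeneric("sessionId", function(object) standardGeneric("sessionId"))
#' @rdname accessors
#' @export
setMethod("sessionId", "SessionRecord", function(object) object@sessionId)

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setMethod("samplingRate", "SessionRecord", function(object) object@samplingRate)
#' @rdname accessors
#' @export
setMethod("samplingRate", "EpochSet", function(object) object@samplingRate)

#' @rdname accessors
#' @export
setGeneric("epochData", function(object) standardGeneric("epochData"))
#' @rdname accessors
#' @export
setMethod("epochData", "EpochSet", function(object) object@data)

#' @rdname accessors
#' @export
setGeneric("epochInfo", function(object) standardGeneric("epochInfo"))
#' @rdname accessors
#' @export
setMethod("epochInfo", "EpochSet", function(object) object@info)

#' @rdname accessors
#' @export
setGeneric("nEpochs", function(object) standardGeneric("nEpochs"))
#' @rdname accessors
#' @export
setMethod("nEpochs", "EpochSet", function(object) dim(object@data)[3])

#' @rdname accessors
#' @export
setGeneric("meanAccuracy", function(object) standardGeneric("meanAccuracy"))
#' @rdname accessors
#' @export
setMethod("meanAccuracy", "ClassifierReport",
          function(object) object@meanAccuracy)

#' @rdname accessors
#' @export
setGeneric("foldAccuracies", function(object) standardGeneric("foldAccuracies"))
#' @rdname accessors
#' @export
setMethod("foldAccuracies", "ClassifierReport",
          function(object) object@foldAccuracies)

#' @rdname accessors
#' @export
setGeneric("confusionMatrix", function(object) standardGeneric("confusionMatrix"))
#' @rdname accessors
#' @export
setMethod("confusionMatrix", "ClassifierReport",
          function(object) object@confusion)

#' @rdname accessors
#' @export
setGeneric("nullAccuracies", function(object) standardGeneric("nullAccuracies"))
#' @rdname accessors
#' @export
setMethod("nullAccuracies", "ClassifierReport",
          function(object) object@nullAccuracies)

#' @rdname accessors
#' @export
setGeneric("netTable", function(object) standardGeneric("netTable"))
#' @rdname accessors
#' @export
setMethod("netTable", "GCNetwork", function(object) object@net)

#' @rdname accessors
#' @export
setGeneric("normalizedTable", function(object) standardGeneric("normalizedTable"))
#' @rdname accessors
#' @export
setMethod("normalizedTable", "GCNetwork", function(object) object@normalized)

#' @rdname accessors
#' @export
setGeneric("gcEstimates", function(object) standardGeneric("gcEstimates"))
#' @rdname accessors
#' @export
setMethod("gcEstimates", "GCNetwork", function(object) object@estimates)

#' @rdname accessors
#' @export
setGeneric("directedEdges", function(object) standardGeneric("directedEdges"))
#' @rdname accessors
#' @export
setMethod("directedEdges", "GCNetwork", function(object) object@directed)

# ---- show methods ---------------------------------------------------------

setMethod("show", "SessionRecord", function(object) {
  cat(sprintf(
    "SessionRecord '%s': %s, day %d\n  %d channels x %d samples @ %g Hz (%.1f s)\n",
    object@sessionId, object@taskType, object@dayIndex,
    nrow(object@lfp), ncol(object@lfp), object@samplingRate,
    ncol(object@lfp) / object@samplingRate))
  tab <- table(object@channelMap$roi)
  cat("  channels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      sprintf("(M1 direct: %d)\n", sum(object@channelMap$direct_unit)))
  cat(sprintf("  trials: %d (%d successful)\n",
              nrow(object@trials),
              if (nrow(object@trials)) sum(object@trials$success) else 0L))
})

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@data)
  cat(sprintf("EpochSet: %d epochs x %d channels x %d samples (%g s @ %g Hz)\n",
              d[3], d[1], d[2], object@windowWidth, object@samplingRate))
  ev <- table(object@info$event)
  cat("  events:", paste(sprintf("%s=%d", names(ev), ev), collapse = ", "),
      "\n")
})

setMethod("show", "ClassifierReport", function(object) {
  cat(sprintf("ClassifierReport (%s, %d classes): mean accuracy %.3f\n",
              toupper(object@modelKind), length(object@classes),
              object@meanAccuracy))
  cat(sprintf("  folds: %d; permutation null: %d draws%s\n",
              length(object@foldAccuracies), length(object@nullAccuracies),
              if (is.na(object@pVsChance)) ""
              else sprintf("; p vs chance = %.3g", object@pVsChance)))
})

setMethod("show", "GCNetwork", function(object) {
  cat(sprintf("GCNetwork: %d day-level estimates, AR order %d\n",
              nrow(object@estimates), object@arOrder))
  if (nrow(object@directed)) {
    sig <- object@directed[object@directed$significant, , drop = FALSE]
    if (nrow(sig)) {
      cat("  significantly directed edges:\n")
      for (i in seq_len(nrow(sig)))
        cat(sprintf("    %s -> %s [%s, %s] net=%.3f p.corr=%.3g\n",
                    sig$source[i], sig$target[i], sig$task_type[i],
                    sig$event[i], sig$mean_net[i], sig$p_corrected[i]))
    } else cat("  no significantly directed edges\n")
  }
})

setMethod("show", "KalmanDecoder", function(object) {
  cat(sprintf("KalmanDecoder: %d units, state dim %d, bin %g s\n",
              nrow(object@C), nrow(object@A), object@binWidth))
})
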