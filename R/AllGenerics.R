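#' @rdname ReferencePanel-accessors
#' @export
setGeneric("panelChrom", function(x) standardGeneric("panelChrom"))
#' @rdname ReferencePanel-accessors
#' @export
setGeneric("panelPositions", function(x) standardGeneric("panelPositions"))
#' @rdname ReferencePanel-accessors
#' @export
setGeneric("panelAlleles", function(x) standardGeneric("panelAlleles"))
#' @rdname ReferencePanel-accessors
#' @export
setGeneric("haplotypeMatrix", function(x) standardGeneric("haplotypeMatrix"))
#' @rdname ReferencePanel-accessors
#' @export
setGeneric("panelPopulations", function(x) standardGeneric("panelPopulations"))
#' @rdname ReferencePanel-accessors
#' @export
setGeneric("nHaplotypes", function(x) standardGeneric("nHaplotypes"))
#' @rdname ReferencePanel-accessors
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))

#' @rdname SampleReads-accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))
#' @rdname SampleReads-accessors
#' @export
setGeneric("samplePloidy", function(x) standardGeneric("samplePloidy"))
#' @rdname SampleReads-accessors
#' @export
setGeneric("readTable", function(x) standardGeneric("readTable"))
#' @rdname SampleReads-accessors
#' @export
setGeneric("obsTable", function(x) standardGeneric("obsTable"))

#' Accessors for ReferencePanel
#'
#' `panelChrom`, `panelPositions`, `panelAlleles` (data.frame of pos/ref/alt),
#' `haplotypeMatrix`, `panelPopulations`, `nHaplotypes` and `nSites` expose
#' the slots of a [ReferencePanel-class] without direct slot access.
#'
#' @param x a `ReferencePanel`.
#' @return the corresponding component.
#' @name ReferencePanel-accessors
NULL

setMethod("panelChrom", "ReferencePanel", function(x) x@chrom)
setMethod("panelPositions", "ReferencePanel", function(x) x@positions)
setMethod("panelAlleles", "ReferencePanel", function(x) {
  data.frame(pos = x@positions, ref = x@ref, alt = x@alt)
})
setMethod("haplotypeMatrix", "ReferencePanel", function(x) x@haplotypes)
setMethod("panelPopulations", "ReferencePanel", function(x) x@populations)
setMethod("nHaplotypes", "ReferencePanel", function(x) nrow(x@haplotypes))
setMethod("nSites", "ReferencePanel", function(x) length(x@positions))

#' Accessors for SampleReads
#'
#' `sampleId`, `samplePloidy`, `readTable` (per-read table with spans and
#' priority scores) and `obsTable` (per-observation table) expose the slots
#' of a [SampleReads-class] object. `panelChrom` also works on `SampleReads`.
#'
#' @param x a `SampleReads`.
#' @return the corresponding component.
#' @name SampleReads-accessors
NULL

setMethod("sampleId", "SampleReads", function(x) x@sampleId)
setMethod("samplePloidy", "SampleReads", function(x) x@ploidy)
setMethod("readTable", "SampleReads", function(x) x@reads)
setMethod("obsTable", "SampleReads", function(x) x@observations)
setMethod("panelChrom", "SampleReads", function(x) x@chrom)
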