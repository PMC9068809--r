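#' @rdname ReferenceGenome-class
#' @param x a \code{ReferenceGenome}.
#' @export
setGeneric("contigs", function(x) standardGeneric("contigs"))

#' @rdname ReferenceGenome-class
#' @export
setGeneric("geneModels", function(x) standardGeneric("geneModels"))

#' @rdname ReferenceGenome-class
#' @export
setGeneric("genomeLength", function(x) standardGeneric("genomeLength"))

#' @rdname GenotypeCallSet-class
#' @param x a \code{GenotypeCallSet}.
#' @export
setGeneric("genotypeId", function(x) standardGeneric("genotypeId"))

#' @rdname GenotypeCallSet-class
#' @export
setGeneric("lineageId", function(x) standardGeneric("lineageId"))

#' @rdname GenotypeCallSet-class
#' @export
setGeneric("variantCalls", function(x) standardGeneric("variantCalls"))

#' @rdname GenotypeCallSet-class
#' @export
setGeneric("callableSites", function(x) standardGeneric("callableSites"))
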