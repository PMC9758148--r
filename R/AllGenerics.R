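#' @rdname LabTable
#' @param x,object a \linkS4class{LabTable} (or other pipeline object).
#' @export
setGeneric("labValues", function(x) standardGeneric("labValues"))

#' @rdname LabTable
#' @export
setGeneric("missingMask", function(x) standardGeneric("missingMask"))

#' @rdname LabTable
#' @export
setGeneric("missingFraction", function(x) standardGeneric("missingFraction"))

#' Extract the complete (ground-truth) table from a synthetic panel
#' @param x a \linkS4class{SyntheticTruth}.
#' @export
setGeneric("completeTable", function(x) standardGeneric("completeTable"))

#' Extract the masked (observed) table from a synthetic panel
#' @param x a \linkS4class{SyntheticTruth}.
#' @export
setGeneric("maskedTable", function(x) standardGeneric("maskedTable"))

#' Planted directed edges of a synthetic panel
#' @param x a \linkS4class{SyntheticTruth} or \linkS4class{DiscreteBN}.
#' @export
setGeneric("trueGraph", function(x) standardGeneric("trueGraph"))

#' Edge list of a DAG-bearing object
#' @param x a \linkS4class{DAG} or \linkS4class{DiscreteBN}.
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))

#' Parent set of a node
#' @param x a \linkS4class{DAG} or \linkS4class{DiscreteBN}.
#' @param node node name.
#' @export
setGeneric("parents", function(x, node) standardGeneric("parents"))

#' Cut points of a discretization scheme
#' @param x a \linkS4class{DiscretizationScheme}.
#' @export
setGeneric("cutpoints", function(x) standardGeneric("cutpoints"))

#' Walkable tree list of an interpretable ensemble
#'
#' Returns each tree as a flat node list (`variable`, `threshold`, children,
#' per-class sample counts) so rule extraction does not depend on any one
#' tree-learning backend.
#' @param x a trained ensemble (e.g. a [ruleForest()] fit).
#' @export
setGeneric("treeWalks", function(x) standardGeneric("treeWalks"))
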