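#' @import methods
NULL

#' Atom table of a structure
#'
#' Accessor for the per-atom table of a \linkS4class{ProteinStructure}
#' (one row per heavy atom unless hydrogens were kept).
#'
#' @param x a \code{ProteinStructure}.
#' @return a \code{data.frame} with columns \code{atom_name}, \code{element},
#'   \code{residue_name}, \code{chain_id}, \code{residue_seq}, \code{insert},
#'   \code{x}, \code{y}, \code{z}, \code{occupancy}, \code{is_hydrogen}.
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname atoms
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' Structure identifier
#' @param x an object carrying a source identifier.
#' @return a character scalar (opaque; prefixes such as \code{"AF2_"} are
#'   preserved untouched).
#' @export
setGeneric("sourceId", function(x) standardGeneric("sourceId"))

#' EC label attached to an object
#' @param x an object carrying an optional EC label.
#' @return dotted EC string or \code{NA_character_}.
#' @export
setGeneric("ecLabel", function(x) standardGeneric("ecLabel"))

#' @rdname ecLabel
#' @param value replacement label.
#' @export
setGeneric("ecLabel<-", function(x, value) standardGeneric("ecLabel<-"))

#' Residue keys of a structure or selection
#'
#' A residue key is \code{"<chain>|<residue_seq><insert>"}; keys are unique
#' per residue and ordered as in the underlying file.
#'
#' @param x a \code{ProteinStructure} or \code{SiteSelection}.
#' @return character vector of residue keys.
#' @export
setGeneric("residueKeys", function(x) standardGeneric("residueKeys"))
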