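# Frame lookup, identifier resolution, and sequence access.

#' Frame accessors
#'
#' Low-level access to a [KnowledgeBase-class]: frame ids by class, a frame's
#' class/name/synonyms, and slot values.
#'
#' @param kb A [KnowledgeBase-class].
#' @param class Optional frame class name.
#' @param id A frame id.
#' @param slot A slot name.
#' @return `frameIds`: character vector of ids (sorted). `frameClass`,
#'   `frameName`: single strings. `frameSynonyms`: character vector.
#'   `slotValues`: character vector of slot values (frame ids for relation
#'   slots, literal strings otherwise); empty when the slot is unset.
#' @export
frameIds <- function(kb, class = NULL) {
  if (is.null(class)) return(sort(names(kb@frames)))
  if (!class %in% kbClasses()) kgArgumentError("unknown class '%s'", class)
  unname(sort(kb@index$byClass[[class]]))
}

.frame <- function(kb, id) {
  f <- kb@frames[[id]]
  if (is.null(f)) kgIntegrityError("no frame with id '%s'", id)
  f
}

#' @rdname frameIds
#' @export
frameClass <- function(kb, id) .frame(kb, id)$class

#' @rdname frameIds
#' @export
frameName <- function(kb, id) .frame(kb, id)$name

#' @rdname frameIds
#' @export
frameSynonyms <- function(kb, id) .frame(kb, id)$synonyms

#' @rdname frameIds
#' @export
slotValues <- function(kb, id, slot) {
  v <- .frame(kb, id)$slots[[slot]]
  if (is.null(v)) character(0) else v
}

# numeric literal slot (start/end/pos)
.slotNum <- function(kb, id, slot) {
  v <- slotValues(kb, id, slot)
  if (!length(v)) return(NA_real_)
  as.numeric(v[1])
}

#' Resolve a token to knowledge-base frames
#'
#' Finds all frames whose id, name, or any synonym equals `token`
#' (case-insensitive). Resolution is tiered: if any frame matches by id, only
#' id matches are returned; otherwise name matches; otherwise synonym
#' matches. Results are ordered by frame id.
#'
#' @param kb A [KnowledgeBase-class].
#' @param token Non-empty string to resolve.
#' @param classFilter Optional frame class restricting the result.
#' @return Character vector of frame ids (possibly empty).
#' @export
resolveFrames <- function(kb, token, classFilter = NULL) {
  if (!is.character(token) || length(token) != 1 || !nzchar(token))
    kgArgumentError("token must be a single non-empty string")
  key <- tolower(token)
  keep <- function(ids) {
    ids <- unique(ids)
    if (!is.null(classFilter))
      ids <- ids[vapply(ids, function(i) kb@frames[[i]]$class == classFilter,
                        logical(1))]
    sort(ids)
  }
  for (map in list(kb@index$idMap, kb@index$nameMap, kb@index$synMap)) {
    hits <- keep(if (is.null(map[[key]])) character(0) else map[[key]])
    if (length(hits)) return(hits)
  }
  character(0)
}

#' Replicon length
#'
#' @param kb A [KnowledgeBase-class].
#' @param replicon Replicon frame id.
#' @return Integer sequence length in bp.
#' @export
repliconLength <- function(kb, replicon) {
  if (!replicon %in% names(kb@sequences))
    kgIntegrityError("replicon '%s' has no sequence", replicon)
  Biostrings::width(kb@sequences)[match(replicon, names(kb@sequences))]
}

#' Extract the nucleotide sequence of a region
#'
#' Returns bases `start..end` (inclusive) of the region's replicon; for minus
#' strand regions the reverse complement is returned. The result always has
#' length `end - start + 1`.
#'
#' @param kb A [KnowledgeBase-class].
#' @param region A [SeqRegion-class].
#' @return Single character string of nucleotides.
#' @export
subsequence <- function(kb, region) {
  stopifnot(is(region, "SeqRegion"))
  len <- repliconLength(kb, region@replicon)
  if (region@start < 1L || region@end > len)
    kgBoundsError("region %d-%d outside replicon %s (1-%d)",
                  region@start, region@end, region@replicon, len)
  s <- Biostrings::subseq(kb@sequences[[region@replicon]],
                          region@start, region@end)
  if (region@strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}
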