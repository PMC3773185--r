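# S4 classes: SeqRegion, KnowledgeBase, Column, Group.

#' @import methods
#' @importFrom Biostrings DNAStringSet DNAString reverseComplement subseq
#' @importClassesFrom Biostrings DNAStringSet
#' @importFrom stats p.adjust setNames
#' @importFrom utils head
NULL

setClassUnion("DNAStringSetOrNULL", c("DNAStringSet", "NULL"))

#' SeqRegion: an interval on a replicon
#'
#' A 1-based, both-ends-inclusive interval `[start, end]` on a named replicon,
#' with a strand ("+" or "-").
#'
#' @slot replicon Frame id of the replicon.
#' @slot start,end Integer coordinates, `1 <= start <= end`.
#' @slot strand "+" or "-".
#' @export
setClass("SeqRegion",
         representation(replicon = "character", start = "integer",
                        end = "integer", strand = "character"),
         validity = function(object) {
           if (length(object@replicon) != 1 || !nzchar(object@replicon))
             return("replicon id must be a single non-empty string")
           if (length(object@start) != 1 || length(object@end) != 1)
             return("start/end must be single integers")
           if (is.na(object@start) || object@start < 1L)
             return("start must be >= 1")
           if (is.na(object@end) || object@end < object@start)
             return("end must be >= start")
           if (!identical(object@strand, "+") && !identical(object@strand, "-"))
             return("strand must be '+' or '-'")
           TRUE
         })

#' Construct a SeqRegion
#'
#' @param replicon Replicon frame id.
#' @param start,end 1-based inclusive coordinates.
#' @param strand "+" (default) or "-".
#' @return A [SeqRegion-class] object.
#' @export
seqRegion <- function(replicon, start, end, strand = "+") {
  new("SeqRegion", replicon = as.character(replicon),
      start = as.integer(start), end = as.integer(end),
      strand = as.character(strand))
}

setMethod("show", "SeqRegion", function(object) {
  cat(sprintf("SeqRegion %s:%d-%d(%s)\n", object@replicon,
              object@start, object@end, object@strand))
})

# canonical string key used for dedup/ordering of region values
.regionKey <- function(r) {
  sprintf("%s:%010d-%010d:%s", r@replicon, r@start, r@end, r@strand)
}

#' KnowledgeBase: a frame store for one organism
#'
#' Holds all frames (genes, proteins, reactions, pathways, compounds,
#' promoters, operons, binding sites, GO terms, replicons, the organism) plus
#' the replicon nucleotide sequences, with lookup indexes by class, id, name
#' and synonym. Construct with [loadKb()] or [generateToyPgdb()].
#'
#' @slot frames Named list of frames; each frame is a list with elements
#'   `id`, `class`, `name`, `synonyms` (character) and `slots` (named list of
#'   character vectors).
#' @slot sequences [Biostrings::DNAStringSet] named by replicon id.
#' @slot index Environment holding the lookup indexes.
#' @export
setClass("KnowledgeBase",
         representation(frames = "list", sequences = "DNAStringSetOrNULL",
                        index = "environment"))

# assemble a KB from a frame list + sequences, building indexes; performs the
# cheap structural checks (unique non-empty ids); full integrity checking is
# validateKb().
.newKb <- function(frames, sequences = NULL) {
  ids <- vapply(frames, function(f) f$id, character(1))
  if (any(!nzchar(ids))) kgIntegrityError("frame with empty id")
  if (anyDuplicated(ids)) {
    kgIntegrityError("duplicate frame id: %s", ids[duplicated(ids)][1])
  }
  names(frames) <- ids
  idx <- new.env(parent = emptyenv())
  cls <- vapply(frames, function(f) f$class, character(1))
  idx$byClass <- split(ids, factor(cls, levels = kbClasses()))
  addTo <- function(env, key, id) {
    key <- tolower(key)
    env[[key]] <- c(env[[key]], id)
  }
  idMap <- new.env(parent = emptyenv())
  nameMap <- new.env(parent = emptyenv())
  synMap <- new.env(parent = emptyenv())
  for (f in frames) {
    addTo(idMap, f$id, f$id)
    if (nzchar(f$name)) addTo(nameMap, f$name, f$id)
    for (s in f$synonyms) if (nzchar(s)) addTo(synMap, s, f$id)
  }
  idx$idMap <- idMap; idx$nameMap <- nameMap; idx$synMap <- synMap
  if (is.null(sequences)) sequences <- Biostrings::DNAStringSet()
  new("KnowledgeBase", frames = frames, sequences = sequences, index = idx)
}

setMethod("show", "KnowledgeBase", function(object) {
  n <- vapply(object@index$byClass, length, integer(1))
  n <- n[n > 0]
  cat(sprintf("KnowledgeBase: %d frames\n", length(object@frames)))
  if (length(n))
    cat(" ", paste(sprintf("%s: %d", names(n), n), collapse = ", "), "\n")
  if (length(object@sequences))
    cat(sprintf("  replicon sequence(s): %s\n",
                paste(sprintf("%s (%d bp)", names(object@sequences),
                              Biostrings::width(object@sequences)),
                      collapse = ", ")))
})

#' Column of a Group
#'
#' Columns other than the member column: stored user data, property columns
#' (raw KB slot values) and transform columns (semantic transformations).
#' Property and transform columns record their provenance in `spec` so they
#' can be recomputed against a KB.
#'
#' @slot header Column header string.
#' @slot kind One of "stored", "property", "transform".
#' @slot valueType One of "ref", "number", "string", "region", "sequence".
#' @slot spec Provenance: `list(slot=)` for property columns,
#'   `list(transform=, params=)` for transform columns.
#' @slot cells List with one cell per group row; a cell is a (possibly empty)
#'   vector of values, or a list of [SeqRegion-class] for region columns.
#' @export
setClass("Column",
         representation(header = "character", kind = "character",
                        valueType = "character", spec = "list",
                        cells = "list"),
         validity = function(object) {
           if (!object@kind %in% c("stored", "property", "transform"))
             return("kind must be stored/property/transform")
           if (!object@valueType %in% c("ref", "number", "string", "region", "sequence"))
             return("bad valueType")
           TRUE
         })

.newColumn <- function(header, kind, valueType, cells, spec = list()) {
  new("Column", header = header, kind = kind, valueType = valueType,
      spec = spec, cells = cells)
}

#' Group: a knowledge spreadsheet
#'
#' An ordered, duplicate-free collection of members (KB frames of one class,
#' or numbers, strings or sequence regions) plus zero or more columns. Column
#' 1 is always the member column; additional columns are indexed from 2.
#'
#' @slot name,description Strings.
#' @slot memberClass A frame class, "Frame" (mixed frame classes), or one of
#'   "number", "string", "region".
#' @slot members List of member values (frame ids as character scalars,
#'   numbers, strings, or [SeqRegion-class] objects).
#' @slot columns List of [Column-class] objects (column 2 onwards).
#' @slot readOnly TRUE for special groups whose contents mirror the KB.
#' @slot metadata Free-form list (e.g. enrichment tables, import reports).
#' @export
setClass("Group",
         representation(name = "character", description = "character",
                        memberClass = "character", members = "list",
                        columns = "list", readOnly = "logical",
                        metadata = "list"),
         validity = function(object) {
           ok <- c(kbClasses(), "Frame", "number", "string", "region")
           if (!object@memberClass %in% ok)
             return(sprintf("bad memberClass '%s'", object@memberClass))
           keys <- vapply(object@members, .valueKey, character(1))
           if (anyDuplicated(keys))
             return("duplicate members in group")
           for (col in object@columns) {
             if (length(col@cells) != length(object@members))
               return(sprintf("column '%s' has %d cells for %d rows",
                              col@header, length(col@cells),
                              length(object@members)))
           }
           TRUE
         })

# key used for member/cell dedup and identity
.valueKey <- function(v) {
  if (is(v, "SeqRegion")) return(.regionKey(v))
  if (is.numeric(v)) return(sprintf("#%.15g", v))
  as.character(v)
}

.newGroup <- function(name, memberClass, members, columns = list(),
                      description = "", readOnly = FALSE, metadata = list()) {
  new("Group", name = name, description = description,
      memberClass = memberClass, members = members, columns = columns,
      readOnly = readOnly, metadata = metadata)
}

setMethod("show", "Group", function(object) {
  cat(sprintf("Group \"%s\" (%s): %d member(s), %d column(s)%s\n",
              object@name, object@memberClass, length(object@members),
              length(object@columns) + 1L,
              if (object@readOnly) " [read-only]" else ""))
  if (length(object@columns))
    cat("  columns:", paste(vapply(object@columns, function(c) c@header,
                                   character(1)), collapse = ", "), "\n")
  n <- length(object@members)
  shown <- head(seq_len(n), 8L)
  for (i in shown) {
    v <- object@members[[i]]
    cat("  -", if (is(v, "SeqRegion")) .regionKey(v) else as.character(v), "\n")
  }
  if (n > length(shown)) cat(sprintf("  ... %d more\n", n - length(shown)))
})

setMethod("length", "Group", function(x) length(x@members))

#' Group accessors
#'
#' `groupName`, `memberClass` and `memberIds` expose the basic contents of a
#' [Group-class]; `columnHeaders` lists all column headers (member column
#' first); `groupColumn` returns a [Column-class] by user-facing index
#' (column 1 is the member column and cannot be fetched this way).
#'
#' @param g A [Group-class].
#' @param i User-facing column index (2 = first non-member column).
#' @return See individual descriptions.
#' @export
groupName <- function(g) g@name

#' @rdname groupName
#' @export
memberClass <- function(g) g@memberClass

#' @rdname groupName
#' @export
memberIds <- function(g) {
  if (g@memberClass %in% c("number", "string", "region"))
    kgTypeError("group '%s' holds %s values, not frames", g@name, g@memberClass)
  unname(vapply(g@members, as.character, character(1)))
}

#' @rdname groupName
#' @export
columnHeaders <- function(g) {
  c(g@memberClass, vapply(g@columns, function(c) c@header, character(1)))
}

#' @rdname groupName
#' @export
groupColumn <- function(g, i) {
  i <- as.integer(i)
  if (i < 2L || i > length(g@columns) + 1L)
    kgArgumentError("column index %d out of range (2..%d)", i,
                    length(g@columns) + 1L)
  g@columns[[i - 1L]]
}

#' @rdname groupName
#' @export
columnCells <- function(g, i) groupColumn(g, i)@cells

.assertMutable <- function(g) {
  if (isTRUE(g@readOnly))
    kgReadOnlyError("group '%s' is read-only; use copyEditable() first", g@name)
  invisible(g)
}
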