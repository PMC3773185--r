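# groups_core: creation, property columns, column-to-group, set and filter
# algebra, TSV import/export, persistence, special groups.

.VALUE_KINDS <- c("number", "string", "region")

# normalise + validate members for a target class; returns list of values
.checkMembers <- function(kb, members, memberClass) {
  if (is.null(members)) members <- list()
  if (!is.list(members)) members <- as.list(members)
  if (memberClass %in% .VALUE_KINDS) {
    ok <- switch(memberClass,
      number = vapply(members, is.numeric, logical(1)),
      string = vapply(members, is.character, logical(1)),
      region = vapply(members, function(v) is(v, "SeqRegion"), logical(1)))
    if (!all(ok)) kgTypeError("members are not all of kind '%s'", memberClass)
    return(members)
  }
  ids <- vapply(members, function(v) {
    if (!is.character(v) || length(v) != 1)
      kgTypeError("frame group members must be frame ids")
    v
  }, character(1))
  for (id in ids) {
    cls <- frameClass(kb, id)   # errors on unknown id
    if (memberClass != "Frame" && cls != memberClass)
      kgTypeError("member '%s' has class %s, expected %s", id, cls, memberClass)
  }
  as.list(unname(ids))
}

.dedupValues <- function(values) {
  keys <- vapply(values, .valueKey, character(1))
  values[!duplicated(keys)]
}

#' Create a group
#'
#' Builds a [Group-class] from a list of members. Duplicate members are
#' removed preserving first occurrence; members must all share the group's
#' member class (a mixed list is a type error).
#'
#' @param kb A [KnowledgeBase-class] (used to validate frame members; may be
#'   `NULL` for number/string/region groups).
#' @param name Group name.
#' @param members Frame ids (character), numbers, strings or
#'   [SeqRegion-class] objects, as a vector or list.
#' @param memberClass A frame class, "Frame", "number", "string" or
#'   "region". Defaults to the class of the first member.
#' @param description Optional description.
#' @return A [Group-class].
#' @export
createGroup <- function(kb, name, members, memberClass = NULL,
                        description = "") {
  if (!is.list(members)) members <- as.list(members)
  if (is.null(memberClass)) {
    if (!length(members))
      kgArgumentError("memberClass is required for an empty group")
    v <- members[[1]]
    memberClass <- if (is(v, "SeqRegion")) "region"
      else if (is.numeric(v)) "number"
      else frameClass(kb, as.character(v))
  }
  members <- .checkMembers(kb, members, memberClass)
  .newGroup(name, memberClass, .dedupValues(members),
            description = description)
}

#' Add members to a group
#'
#' Appends members not already present; rejects read-only groups.
#'
#' @inheritParams createGroup
#' @param g A [Group-class].
#' @return The extended [Group-class].
#' @export
addMembers <- function(g, members, kb = NULL) {
  .assertMutable(g)
  members <- .checkMembers(kb, members, g@memberClass)
  all <- .dedupValues(c(g@members, members))
  novel <- length(all) - length(g@members)
  g@members <- all
  for (i in seq_along(g@columns)) {
    g@columns[[i]]@cells <- c(g@columns[[i]]@cells,
                              rep(list(.emptyCell(g@columns[[i]]@valueType)),
                                  novel))
  }
  validObject(g)
  g
}

.emptyCell <- function(valueType) {
  switch(valueType, number = numeric(0), region = list(), character(0))
}

# keep rows idx (integer vector) of a group, subsetting all columns
.subsetRows <- function(g, idx) {
  g@members <- g@members[idx]
  g@columns <- lapply(g@columns, function(col) {
    col@cells <- col@cells[idx]
    col
  })
  g
}

# ---- property columns ----------------------------------------------------

#' Add a property column
#'
#' Appends a column holding the raw values of a KB slot for each member
#' (multi-valued cells where the slot is multi-valued). The column records
#' the slot name so it can be recomputed. Unknown slots raise a schema error
#' listing the valid slots for the member class.
#'
#' @param g A [Group-class] of frames.
#' @param kb A [KnowledgeBase-class].
#' @param slot Slot name (see [slotsForClass()]).
#' @return The [Group-class] with one more column.
#' @export
addPropertyColumn <- function(g, kb, slot) {
  .assertMutable(g)
  if (g@memberClass %in% c(.VALUE_KINDS, "Frame"))
    kgSchemaError("property columns need a single-frame-class group")
  valid <- slotsForClass(g@memberClass)
  if (!slot %in% valid)
    kgSchemaError("slot '%s' not defined for class %s; valid slots: %s",
                  slot, g@memberClass, paste(valid, collapse = ", "))
  def <- .slotDef(slot)
  vt <- if (def$kind == "ref") "ref" else def$kind
  cells <- lapply(g@members, function(id) {
    v <- slotValues(kb, id, slot)
    if (vt == "ref") sort(v)
    else if (vt == "number") as.numeric(v)
    else v
  })
  g@columns <- c(g@columns, .newColumn(slot, "property", vt, cells,
                                       spec = list(slot = slot)))
  validObject(g)
  g
}

#' Delete a (non-member) column
#'
#' @param g A [Group-class].
#' @param i User-facing column index (>= 2).
#' @return The [Group-class] without that column.
#' @export
deleteColumn <- function(g, i) {
  .assertMutable(g)
  groupColumn(g, i)  # bounds check
  g@columns[[as.integer(i) - 1L]] <- NULL
  g
}

#' Recompute a derived column from its provenance spec
#'
#' Property and transform columns carry the slot/transform they were built
#' from; this recomputes the column against a KB, e.g. after reloading a
#' saved group.
#'
#' @param g A [Group-class].
#' @param kb A [KnowledgeBase-class].
#' @param i User-facing column index (>= 2).
#' @return The [Group-class] with column `i` recomputed in place.
#' @export
recomputeColumn <- function(g, kb, i) {
  col <- groupColumn(g, i)
  if (col@kind == "stored")
    kgArgumentError("column '%s' is stored data, not derived", col@header)
  tmp <- if (col@kind == "property")
    addPropertyColumn(.dropColumns(g), kb, col@spec$slot)
  else
    addTransformColumn(.dropColumns(g), kb, col@spec$transform,
                       params = col@spec$params)
  g@columns[[as.integer(i) - 1L]] <- tmp@columns[[1L]]
  g
}

.dropColumns <- function(g) { g@columns <- list(); g@readOnly <- FALSE; g }

# ---- column to group -----------------------------------------------------

#' Form a new group from the values of one column
#'
#' Collects the non-redundant union of all values in a frame-valued column
#' as a new group (members id-ordered), and attaches a reverse-mapping
#' column: for each new member, the original group members whose cell
#' contained it.
#'
#' @param g A [Group-class].
#' @param kb A [KnowledgeBase-class].
#' @param i User-facing column index (>= 2) of a frame-valued column.
#' @param name Name for the new group (default auto-generated).
#' @return A [Group-class] of the column's value class.
#' @export
columnToGroup <- function(g, kb, i, name = NULL) {
  col <- groupColumn(g, i)
  if (col@valueType != "ref")
    kgTypeError("column '%s' holds %s values, not frames",
                col@header, col@valueType)
  vals <- sort(unique(unlist(col@cells, use.names = FALSE)))
  if (is.null(name)) name <- sprintf("%s of %s", col@header, g@name)
  if (!length(vals)) {
    out <- .newGroup(name, "Frame", list())
    out@columns <- list(.newColumn(sprintf("%s members", g@name),
                                   "stored",
                                   if (g@memberClass %in% .VALUE_KINDS)
                                     g@memberClass else "ref",
                                   list()))
    return(out)
  }
  cls <- unique(vapply(vals, function(v) frameClass(kb, v), character(1)))
  if (length(cls) != 1)
    kgTypeError("column '%s' mixes frame classes: %s", col@header,
                paste(cls, collapse = ", "))
  memKeys <- vapply(g@members, .valueKey, character(1))
  rev <- lapply(vals, function(v) {
    hit <- vapply(col@cells, function(cell) v %in% cell, logical(1))
    if (g@memberClass %in% .VALUE_KINDS && g@memberClass != "region")
      unlist(g@members[hit])
    else memKeys[hit]
  })
  out <- .newGroup(name, cls, as.list(vals))
  out@columns <- list(.newColumn(sprintf("%s members", g@name), "stored",
                                 if (g@memberClass == "number") "number"
                                 else if (g@memberClass == "region") "string"
                                 else if (g@memberClass == "string") "string"
                                 else "ref",
                                 rev))
  validObject(out)
  out
}

# ---- set operations ------------------------------------------------------

.checkSameClass <- function(a, b) {
  if (!identical(a@memberClass, b@memberClass))
    kgTypeError("member class mismatch: %s vs %s",
                a@memberClass, b@memberClass)
}

#' Set operations on groups
#'
#' Standard set semantics on members of two same-class groups. The union
#' keeps `a`'s order followed by `b`'s novel members; intersection and
#' difference keep `a`'s order. Non-member columns are dropped from the
#' result (derived columns are recomputable via their provenance).
#'
#' @param a,b [Group-class] objects sharing a member class.
#' @param name Optional result name (auto-generated otherwise).
#' @return A new [Group-class].
#' @export
groupUnion <- function(a, b, name = NULL) {
  .checkSameClass(a, b)
  .newGroup(name %||% sprintf("(%s union %s)", a@name, b@name),
            a@memberClass, .dedupValues(c(a@members, b@members)))
}

#' @rdname groupUnion
#' @export
groupIntersection <- function(a, b, name = NULL) {
  .checkSameClass(a, b)
  bk <- vapply(b@members, .valueKey, character(1))
  keep <- vapply(a@members, function(v) .valueKey(v) %in% bk, logical(1))
  .newGroup(name %||% sprintf("(%s intersect %s)", a@name, b@name),
            a@memberClass, a@members[keep])
}

#' @rdname groupUnion
#' @export
groupDifference <- function(a, b, name = NULL) {
  .checkSameClass(a, b)
  bk <- vapply(b@members, .valueKey, character(1))
  keep <- vapply(a@members, function(v) !(.valueKey(v) %in% bk), logical(1))
  .newGroup(name %||% sprintf("(%s minus %s)", a@name, b@name),
            a@memberClass, a@members[keep])
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# ---- filters -------------------------------------------------------------

#' Filter a group by member name
#'
#' Keeps rows whose member's name or any synonym contains `substring`
#' (case-insensitive). All columns are preserved. The empty substring keeps
#' every row.
#'
#' @param g A [Group-class] of frames.
#' @param kb A [KnowledgeBase-class].
#' @param substring String to search for.
#' @return The filtered [Group-class].
#' @export
filterByName <- function(g, kb, substring) {
  if (g@memberClass %in% .VALUE_KINDS)
    kgTypeError("name filter needs a group of frames")
  pat <- tolower(substring)
  keep <- vapply(g@members, function(id) {
    hay <- tolower(c(frameName(kb, id), frameSynonyms(kb, id)))
    any(grepl(pat, hay, fixed = TRUE)) || !nzchar(pat)
  }, logical(1))
  out <- .subsetRows(g, which(keep))
  out@readOnly <- FALSE
  out@name <- sprintf("%s [name ~ \"%s\"]", g@name, substring)
  out
}

#' Filter a group on a numeric column
#'
#' Keeps rows for which any value in the chosen numeric column satisfies the
#' comparison (existential semantics on multi-valued cells); rows with empty
#' cells never satisfy it.
#'
#' @param g A [Group-class].
#' @param i User-facing index of a numeric column (>= 2).
#' @param op One of `">"`, `">="`, `"<"`, `"<="`, `"="`.
#' @param bound Numeric threshold.
#' @return The filtered [Group-class].
#' @export
filterByThreshold <- function(g, i, op, bound) {
  col <- groupColumn(g, i)
  if (col@valueType != "number")
    kgTypeError("column '%s' is not numeric", col@header)
  op <- c(">" = ">", ">=" = ">=", "≥" = ">=", "<" = "<",
          "<=" = "<=", "≤" = "<=", "=" = "==", "==" = "==")[[op]]
  if (is.null(op) || is.na(op)) kgArgumentError("bad comparison operator")
  f <- match.fun(op)
  keep <- vapply(col@cells, function(cell)
    length(cell) > 0 && any(f(cell, bound)), logical(1))
  out <- .subsetRows(g, which(keep))
  out@readOnly <- FALSE
  out@name <- sprintf("%s [%s %s %s]", g@name, col@header, op, bound)
  out
}

# ---- TSV import / export -------------------------------------------------

#' Import a group from a tab-delimited file
#'
#' Column 1 holds identifiers, common names or synonyms of KB objects;
#' tokens are resolved case-insensitively via [resolveFrames()] with the
#' class filter. Remaining columns are kept as stored data columns (numeric
#' when every non-empty entry parses as a number). A header line is
#' auto-detected (first row treated as a header when its first token
#' resolves to nothing and the file has at least 2 columns) unless `header`
#' says otherwise. Unresolved and ambiguous tokens are recorded in the
#' import report (`metadata(g)$importReport`); ambiguous tokens take the
#' id-ordered first match.
#'
#' @param kb A [KnowledgeBase-class].
#' @param path Tab-delimited input file.
#' @param memberClass Frame class the identifiers must resolve to.
#' @param header "auto" (default), "yes" or "no".
#' @param name Group name (defaults to the file name).
#' @return A [Group-class]; the import report sits in its `metadata` slot.
#' @export
importGroupTsv <- function(kb, path, memberClass, header = "auto",
                           name = NULL) {
  if (!file.exists(path)) kgStop("kgIOError", "cannot read file '%s'", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines)]
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  rows <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- max(c(1L, vapply(rows, length, integer(1))))
  hasHeader <- switch(header,
    yes = TRUE, no = FALSE,
    auto = length(rows) > 0 && ncol >= 2L &&
      length(resolveFrames(kb, rows[[1]][1], memberClass)) == 0L,
    kgArgumentError("header must be auto/yes/no"))
  headers <- if (hasHeader) {
    h <- rows[[1]]; rows <- rows[-1]
    c(h, sprintf("column %d", seq_len(ncol)))[seq_len(ncol)]
  } else c(memberClass, sprintf("column %d", seq.int(2L, length.out = ncol - 1L)))

  memberIds <- character(0)
  data <- list()
  report <- list(unresolved = character(0), ambiguous = list(),
                 duplicates = character(0))
  for (r in rows) {
    token <- trimws(r[1])
    if (!nzchar(token)) next
    hits <- resolveFrames(kb, token, memberClass)
    if (!length(hits)) {
      report$unresolved <- c(report$unresolved, token)
      next
    }
    if (length(hits) > 1) report$ambiguous[[token]] <- hits
    id <- hits[1]
    if (id %in% memberIds) {
      report$duplicates <- c(report$duplicates, token)
      next
    }
    memberIds <- c(memberIds, id)
    data[[length(data) + 1L]] <-
      c(r[-1], rep("", ncol - 1L))[seq_len(ncol - 1L)]
  }
  if (!length(memberIds))
    warning("no tokens in '", path, "' resolved to ", memberClass,
            " frames; group is empty")
  g <- .newGroup(name, memberClass, as.list(memberIds))
  for (j in seq_len(ncol - 1L)) {
    raw <- vapply(data, `[`, character(1), j)
    num <- suppressWarnings(as.numeric(raw))
    numeric <- length(raw) > 0 && all(!nzchar(raw) | !is.na(num))
    cells <- if (numeric)
      lapply(seq_along(raw), function(k)
        if (nzchar(raw[k])) num[k] else numeric(0))
    else
      lapply(raw, function(v) if (nzchar(v)) v else character(0))
    g@columns <- c(g@columns,
                   .newColumn(headers[j + 1L], "stored",
                              if (numeric) "number" else "string", cells))
  }
  g@metadata$importReport <- report
  validObject(g)
  g
}

.renderValue <- function(kb, vt, v) {
  if (vt == "region") return(sprintf("%s:%d-%d(%s)", v@replicon, v@start,
                                     v@end, v@strand))
  if (vt == "ref") {
    nm <- frameName(kb, v)
    return(if (nzchar(nm)) nm else v)
  }
  if (vt == "number") {
    return(vapply(v, function(x) format(x, scientific = FALSE, trim = TRUE),
                  character(1)))
  }
  as.character(v)
}

.renderCell <- function(kb, vt, cell, sep) {
  if (vt == "region")
    return(paste(vapply(cell, function(r) .renderValue(kb, vt, r),
                        character(1)), collapse = sep))
  if (vt == "ref")
    return(paste(vapply(cell, function(v) .renderValue(kb, vt, v),
                        character(1)), collapse = sep))
  paste(.renderValue(kb, vt, cell), collapse = sep)
}

#' Export a group to a tab-delimited file
#'
#' Writes a header row of column headers and one line per row. Frames are
#' rendered as their display name (falling back to the id), regions as
#' `replicon:start-end(strand)`, and multi-valued cells are joined with
#' `sep` (default `" // "`). Output is deterministic.
#'
#' @param g A [Group-class].
#' @param kb A [KnowledgeBase-class].
#' @param path Output file path.
#' @param sep Multi-value join string.
#' @return `path`, invisibly.
#' @export
exportGroupTsv <- function(g, kb, path, sep = " // ") {
  memVt <- if (g@memberClass == "region") "region"
    else if (g@memberClass %in% .VALUE_KINDS) g@memberClass
    else "ref"
  out <- paste(columnHeaders(g), collapse = "\t")
  for (r in seq_along(g@members)) {
    fields <- .renderCell(kb, memVt, if (memVt == "region")
      list(g@members[[r]]) else g@members[[r]], sep)
    for (col in g@columns)
      fields <- c(fields, .renderCell(kb, col@valueType, col@cells[[r]], sep))
    out <- c(out, paste(fields, collapse = "\t"))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(out, con, useBytes = TRUE)
  invisible(path)
}

# ---- persistence ---------------------------------------------------------

.GROUP_FORMAT <- "kgroups-group"
.GROUP_VERSION <- 1L

.serializeCell <- function(vt, cell) {
  if (vt == "region")
    lapply(cell, function(r) list(replicon = r@replicon, start = r@start,
                                  end = r@end, strand = r@strand))
  else as.list(cell)
}

.deserializeCell <- function(vt, cell) {
  if (vt == "region")
    lapply(cell, function(r) seqRegion(r$replicon, r$start, r$end, r$strand))
  else if (vt == "number") as.numeric(unlist(cell, use.names = FALSE))
  else as.character(unlist(cell, use.names = FALSE))
}

#' Save / load a group
#'
#' Groups persist as versioned JSON: members, all columns with their
#' provenance specs, name, description and the read-only flag round-trip
#' losslessly. Loading a file of an unsupported version raises a version
#' error; truncated files raise a parse error.
#'
#' @param g A [Group-class].
#' @param path File path (conventionally `*.grp`).
#' @return `saveGroup`: `path` invisibly. `loadGroup`: the [Group-class].
#' @export
saveGroup <- function(g, path) {
  memVt <- if (g@memberClass == "region") "region"
    else if (g@memberClass == "number") "number" else "string"
  obj <- list(
    format = .GROUP_FORMAT, version = .GROUP_VERSION,
    name = g@name, description = g@description,
    memberClass = g@memberClass, readOnly = g@readOnly,
    members = .serializeCell(memVt, if (memVt == "region") g@members
                             else unlist(g@members, use.names = FALSE)),
    columns = lapply(g@columns, function(col) list(
      header = col@header, kind = col@kind, valueType = col@valueType,
      spec = col@spec,
      cells = lapply(col@cells, function(c) .serializeCell(col@valueType, c)))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname saveGroup
#' @export
loadGroup <- function(path) {
  if (!file.exists(path)) kgStop("kgIOError", "cannot read file '%s'", path)
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e)
                    kgParseError("cannot parse group file '%s': %s",
                                 path, conditionMessage(e)))
  if (!identical(obj$format, .GROUP_FORMAT))
    kgParseError("'%s' is not a kgroups group file", path)
  if (!identical(as.integer(obj$version), .GROUP_VERSION))
    kgVersionError("group file version %s is not supported (expected %d)",
                   obj$version, .GROUP_VERSION)
  memVt <- if (obj$memberClass == "region") "region"
    else if (obj$memberClass == "number") "number" else "string"
  members <- .deserializeCell(memVt, obj$members)
  if (memVt != "region") members <- as.list(members)
  cols <- lapply(obj$columns, function(c)
    .newColumn(c$header, c$kind, c$valueType,
               lapply(c$cells, function(cell)
                 .deserializeCell(c$valueType, cell)),
               spec = lapply(c$spec, function(x)
                 if (is.list(x)) x else x)))
  g <- .newGroup(obj$name, obj$memberClass, members, columns = cols,
                 description = obj$description %||% "",
                 readOnly = isTRUE(obj$readOnly))
  validObject(g)
  g
}

# ---- special groups ------------------------------------------------------

#' Special (computed) groups and editable copies
#'
#' `specialGroup` returns the read-only group of all KB frames of a class
#' (e.g. all genes of the organism); its contents mirror the current KB and
#' it rejects every mutation. `copyEditable` returns a mutable snapshot.
#'
#' @param kb A [KnowledgeBase-class].
#' @param class A frame class name.
#' @param g A [Group-class].
#' @return A [Group-class].
#' @export
specialGroup <- function(kb, class) {
  ids <- frameIds(kb, class)
  .newGroup(sprintf("All %s", class), class, as.list(ids),
            description = sprintf("All %s frames of the knowledge base",
                                  class),
            readOnly = TRUE)
}

#' @rdname specialGroup
#' @export
copyEditable <- function(g) {
  g@readOnly <- FALSE
  g@name <- sprintf("Copy of %s", g@name)
  g
}
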