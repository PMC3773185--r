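# KB interchange format: load, save, validate.
#
# Format: UTF-8 text, header "##kgroups-kb 1"; one record per frame:
#   frame<TAB>Class<TAB>id<TAB>name<TAB>syn1,syn2
#   slot<TAB>slot-name<TAB>value[,value...]
# followed by an optional "##fasta" section holding replicon sequences.

.KB_HEADER <- "##kgroups-kb 1"

#' Load a knowledge base from its interchange file
#'
#' Parses a KB interchange file (as written by [saveKb()] or the `kb
#' generate` CLI command), resolves all frame references, and runs the full
#' integrity validator. Malformed input raises a parse error naming the line;
#' a dangling frame reference raises an integrity error naming the reference.
#'
#' @param path Path to a KB interchange file.
#' @return A validated [KnowledgeBase-class].
#' @seealso [saveKb()], [validateKb()], [generateToyPgdb()]
#' @export
loadKb <- function(path) {
  if (!file.exists(path)) kgStop("kgIOError", "cannot read KB file '%s'", path)
  lines <- readLines(path, encoding = "UTF-8")
  if (!length(lines) || !startsWith(lines[1], "##kgroups-kb"))
    kgParseError("%s:1: missing '##kgroups-kb' header", path)
  if (!identical(lines[1], .KB_HEADER))
    kgVersionError("%s:1: unsupported KB format version: '%s'", path, lines[1])

  frames <- list()
  cur <- NULL
  i <- 2L
  nl <- length(lines)
  while (i <= nl && !identical(lines[i], "##fasta")) {
    ln <- lines[i]
    if (!nzchar(ln) || startsWith(ln, "#")) { i <- i + 1L; next }
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (identical(f[1], "frame")) {
      if (length(f) < 3L) kgParseError("%s:%d: malformed frame line", path, i)
      if (!is.null(cur)) frames[[length(frames) + 1L]] <- cur
      cls <- f[2]
      if (!cls %in% kbClasses())
        kgParseError("%s:%d: unknown frame class '%s'", path, i, cls)
      syn <- if (length(f) >= 5L && nzchar(f[5]))
        strsplit(f[5], ",", fixed = TRUE)[[1]] else character(0)
      cur <- list(id = f[3], class = cls,
                  name = if (length(f) >= 4L) f[4] else "",
                  synonyms = syn, slots = list())
    } else if (identical(f[1], "slot")) {
      if (is.null(cur))
        kgParseError("%s:%d: slot line before any frame record", path, i)
      if (length(f) != 3L) kgParseError("%s:%d: malformed slot line", path, i)
      def <- .slotDef(f[2])
      if (is.null(def))
        kgParseError("%s:%d: unknown slot '%s'", path, i, f[2])
      if (!cur$class %in% .splitClasses(def$domains))
        kgParseError("%s:%d: slot '%s' not defined for class %s",
                     path, i, f[2], cur$class)
      cur$slots[[f[2]]] <- strsplit(f[3], ",", fixed = TRUE)[[1]]
    } else {
      kgParseError("%s:%d: unrecognised line '%s'", path, i,
                   substr(ln, 1, 40))
    }
    i <- i + 1L
  }
  if (!is.null(cur)) frames[[length(frames) + 1L]] <- cur

  seqs <- NULL
  if (i <= nl) {  # ##fasta section
    i <- i + 1L
    ids <- character(0); chunks <- list(); curseq <- NULL
    while (i <= nl) {
      ln <- lines[i]
      if (startsWith(ln, ">")) {
        ids <- c(ids, sub("^>\\s*", "", ln))
        chunks[[length(ids)]] <- character(0)
      } else if (nzchar(ln)) {
        if (!length(ids)) kgParseError("%s:%d: sequence before '>' header", path, i)
        chunks[[length(ids)]] <- c(chunks[[length(ids)]], ln)
      }
      i <- i + 1L
    }
    if (length(ids)) {
      seqs <- Biostrings::DNAStringSet(vapply(chunks, paste0, character(1),
                                              collapse = ""))
      names(seqs) <- ids
    }
  }

  kb <- .newKb(frames, seqs)
  validateKb(kb)
  kb
}

#' Save a knowledge base to its interchange file
#'
#' Writes a deterministic (id-sorted) interchange file; `loadKb(saveKb(kb))`
#' is content-identical to `kb`.
#'
#' @param kb A [KnowledgeBase-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
saveKb <- function(kb, path) {
  out <- .KB_HEADER
  badval <- function(v) grepl("[\t\n,]", v)
  for (id in sort(names(kb@frames))) {
    f <- kb@frames[[id]]
    if (any(badval(c(f$id, f$name, f$synonyms))))
      kgArgumentError("frame '%s': tabs/commas not allowed in names", f$id)
    out <- c(out, paste("frame", f$class, f$id, f$name,
                        paste(f$synonyms, collapse = ","), sep = "\t"))
    for (s in sort(names(f$slots))) {
      v <- f$slots[[s]]
      if (any(badval(v)))
        kgArgumentError("frame '%s' slot '%s': tabs/commas not allowed", f$id, s)
      out <- c(out, paste("slot", s, paste(v, collapse = ","), sep = "\t"))
    }
  }
  if (length(kb@sequences)) {
    out <- c(out, "##fasta")
    for (nm in sort(names(kb@sequences))) {
      out <- c(out, paste0(">", nm))
      s <- as.character(kb@sequences[[nm]])
      starts <- seq(1L, nchar(s), by = 70L)
      out <- c(out, substring(s, starts, pmin(starts + 69L, nchar(s))))
    }
  }
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}

# ---- validation ----------------------------------------------------------

.refCheck <- function(kb) {
  for (f in kb@frames) {
    for (s in names(f$slots)) {
      def <- .slotDef(s)
      if (is.null(def))
        kgIntegrityError("frame '%s': unknown slot '%s'", f$id, s)
      if (!f$class %in% .splitClasses(def$domains))
        kgIntegrityError("frame '%s' (%s): slot '%s' not allowed",
                         f$id, f$class, s)
      vals <- f$slots[[s]]
      if (def$kind == "ref") {
        rng <- .splitClasses(def$range)
        for (v in vals) {
          t <- kb@frames[[v]]
          if (is.null(t))
            kgIntegrityError("frame '%s' slot '%s': dangling reference '%s'",
                             f$id, s, v)
          if (!t$class %in% rng)
            kgIntegrityError("frame '%s' slot '%s': '%s' has class %s, expected %s",
                             f$id, s, v, t$class, def$range)
        }
      } else if (def$kind == "number") {
        if (anyNA(suppressWarnings(as.numeric(vals))))
          kgIntegrityError("frame '%s' slot '%s': non-numeric value", f$id, s)
      }
    }
  }
}

.symmetryCheck <- function(kb) {
  for (f in kb@frames) {
    for (s in names(f$slots)) {
      def <- .slotDef(s)
      if (def$kind != "ref") next
      inv <- def$inverse
      for (v in f$slots[[s]]) {
        back <- kb@frames[[v]]$slots[[inv]]
        if (is.null(back) || !f$id %in% back)
          kgIntegrityError("relation asymmetry: %s -%s-> %s lacks inverse %s",
                           f$id, s, v, inv)
      }
    }
  }
}

.dagCheck <- function(edges, what) {
  # edges: 2-col character matrix child->parent
  if (!nrow(edges)) return(invisible())
  g <- igraph::graph_from_edgelist(edges, directed = TRUE)
  if (!igraph::is_dag(g)) kgIntegrityError("%s graph contains a cycle", what)
}

.goCheck <- function(kb) {
  terms <- kb@index$byClass[["GOTerm"]]
  if (!length(terms)) return(invisible())
  ont <- character(0)
  edges <- NULL
  for (id in terms) {
    o <- slotValues(kb, id, "ontology")
    if (length(o) != 1 || !o %in% .GO_ONTOLOGIES)
      kgIntegrityError("GO term '%s' must belong to exactly one ontology", id)
    ont[id] <- o
    for (p in slotValues(kb, id, "is-a")) {
      edges <- rbind(edges, c(id, p))
    }
  }
  for (e in seq_len(NROW(edges))) {
    if (ont[edges[e, 1]] != ont[edges[e, 2]])
      kgIntegrityError("GO is-a edge %s -> %s crosses ontologies",
                       edges[e, 1], edges[e, 2])
  }
  if (!is.null(edges)) .dagCheck(edges, "GO is-a")
  for (o in unique(ont)) {
    ids <- names(ont)[ont == o]
    roots <- ids[vapply(ids, function(i) length(slotValues(kb, i, "is-a")) == 0,
                        logical(1))]
    if (length(roots) != 1)
      kgIntegrityError("ontology '%s' has %d roots, expected 1", o, length(roots))
  }
}

.pathwayClassCheck <- function(kb) {
  edges <- NULL
  for (id in kb@index$byClass[["PathwayClass"]]) {
    p <- slotValues(kb, id, "parent-class")
    if (length(p) > 1)
      kgIntegrityError("pathway class '%s' has %d parents (tree requires <= 1)",
                       id, length(p))
    if (length(p)) edges <- rbind(edges, c(id, p))
  }
  if (!is.null(edges)) .dagCheck(edges, "pathway-class")
}

.coordCheck <- function(kb) {
  for (id in c(kb@index$byClass[["Gene"]], kb@index$byClass[["BindingSite"]])) {
    rep <- slotValues(kb, id, "replicon")
    if (!length(rep)) next
    len <- repliconLength(kb, rep[1])
    st <- .slotNum(kb, id, "start"); en <- .slotNum(kb, id, "end")
    if (is.na(st) || is.na(en) || st < 1 || st > en || en > len)
      kgIntegrityError("feature '%s': coordinates %s..%s violate 1 <= start <= end <= %d",
                       id, st, en, len)
    strand <- slotValues(kb, id, "strand")
    if (length(strand) && !strand[1] %in% c("+", "-"))
      kgIntegrityError("feature '%s': bad strand '%s'", id, strand[1])
  }
  for (id in kb@index$byClass[["Promoter"]]) {
    rep <- slotValues(kb, id, "replicon")
    if (!length(rep)) next
    len <- repliconLength(kb, rep[1])
    p <- .slotNum(kb, id, "pos")
    if (is.na(p) || p < 1 || p > len)
      kgIntegrityError("promoter '%s': pos %s outside replicon", id, p)
  }
}

.literalCheck <- function(kb) {
  for (id in kb@index$byClass[["Reaction"]]) {
    d <- slotValues(kb, id, "direction")
    if (length(d) && !d[1] %in% c("L2R", "R2L", "REV"))
      kgIntegrityError("reaction '%s': bad direction '%s'", id, d[1])
  }
}

#' Validate knowledge-base integrity
#'
#' Asserts all schema invariants: every frame reference resolves and has the
#' declared range class; every relation instance has its inverse; the GO
#' is-a graph is acyclic with each term in exactly one of the three
#' ontologies and a single root per ontology; the pathway-class graph is a
#' single-parent tree; feature coordinates lie within their replicon; strand
#' and direction literals are well-formed.
#'
#' @param kb A [KnowledgeBase-class].
#' @return `TRUE` invisibly; stops with an integrity error otherwise.
#' @export
validateKb <- function(kb) {
  .refCheck(kb)
  .symmetryCheck(kb)
  .goCheck(kb)
  .pathwayClassCheck(kb)
  .coordCheck(kb)
  .literalCheck(kb)
  invisible(TRUE)
}
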