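# Semantic transformations: the domain-specific column operations available
# for each member class, plus group-level compression and flank extraction.

.u <- function(x) {
  if (is.null(x)) return(character(0))
  unname(sort(unique(x)))
}

# gene product plus any complexes it participates in — the enzyme units
# through which a gene's catalytic activity is traced to reactions
.geneUnits <- function(kb, g) {
  p <- slotValues(kb, g, "product")
  .u(c(p, unlist(lapply(p, function(x) slotValues(kb, x, "component-of")))))
}

.geneOperons   <- function(kb, g) .u(slotValues(kb, g, "in-operon"))
.genePromoters <- function(kb, g)
  .u(unlist(lapply(.geneOperons(kb, g),
                   function(o) slotValues(kb, o, "promoter"))))
.geneSites <- function(kb, g)
  .u(unlist(lapply(.genePromoters(kb, g),
                   function(p) slotValues(kb, p, "binding-sites"))))
.geneRegulators <- function(kb, g)
  .u(unlist(lapply(.geneSites(kb, g),
                   function(s) slotValues(kb, s, "bound-by"))))
.geneReactions <- function(kb, g)
  .u(unlist(lapply(.geneUnits(kb, g),
                   function(u) slotValues(kb, u, "catalyzes"))))
.genePathways <- function(kb, g)
  .u(unlist(lapply(.geneReactions(kb, g),
                   function(r) slotValues(kb, r, "in-pathway"))))

.isSigma <- function(kb, prot)
  identical(slotValues(kb, prot, "sigma-factor"), "true")

.geneRegion <- function(kb, g) {
  rep <- slotValues(kb, g, "replicon")
  if (!length(rep)) return(NULL)
  strand <- slotValues(kb, g, "strand")
  seqRegion(rep[1], .slotNum(kb, g, "start"), .slotNum(kb, g, "end"),
            if (length(strand)) strand[1] else "+")
}

# produced/consumed compounds of a reaction under its declared direction;
# reversible reactions count both sides as both
.rxnCompounds <- function(kb, r, mode) {
  d <- slotValues(kb, r, "direction")
  d <- if (length(d)) d[1] else "L2R"
  left <- slotValues(kb, r, "left")
  right <- slotValues(kb, r, "right")
  produced <- switch(d, L2R = right, R2L = left, REV = c(left, right))
  consumed <- switch(d, L2R = left, R2L = right, REV = c(left, right))
  switch(mode,
         produced = .u(produced), consumed = .u(consumed),
         both = .u(c(left, right)),
         kgArgumentError("mode must be produced/consumed/both"))
}

.normMode <- function(params, default = "both") {
  m <- params$mode %||% default
  c(producing = "produced", consuming = "consumed",
    produced = "produced", consumed = "consumed", both = "both")[[m]] %||%
    kgArgumentError("bad mode '%s'", m)
}

.compoundReactions <- function(kb, c, mode) {
  rs <- .u(c(slotValues(kb, c, "left-of"), slotValues(kb, c, "right-of")))
  if (mode == "both") return(rs)
  rs[vapply(rs, function(r) c %in% .rxnCompounds(kb, r, mode), logical(1))]
}

.pathwayEnzymes <- function(kb, p)
  .u(unlist(lapply(slotValues(kb, p, "reactions"),
                   function(r) slotValues(kb, r, "enzymes"))))

.enzymeGenes <- function(kb, e) {
  if (frameClass(kb, e) == "ProteinComplex") {
    pps <- slotValues(kb, e, "components")
  } else pps <- e
  .u(unlist(lapply(pps, function(p) slotValues(kb, p, "gene"))))
}

# ---- transform registry --------------------------------------------------

.ref <- function(fn) list(output = "ref", fn = fn)

.TRANSFORMS <- list(
  Gene = list(
    "regulators" = .ref(function(kb, g, params) .geneRegulators(kb, g)),
    "regulated-genes" = .ref(function(kb, g, params)
      .u(unlist(lapply(.geneUnits(kb, g),
                       function(u) slotValues(kb, u, "regulates"))))),
    "binding-sites" = .ref(function(kb, g, params) .geneSites(kb, g)),
    "tf-binding-sites-upstream" = .ref(function(kb, g, params) {
      s <- .geneSites(kb, g)
      s[vapply(s, function(x)
        any(!vapply(slotValues(kb, x, "bound-by"),
                    function(p) .isSigma(kb, p), logical(1))),
        logical(1))]
    }),
    "promoters" = .ref(function(kb, g, params) .genePromoters(kb, g)),
    "operons" = .ref(function(kb, g, params) .geneOperons(kb, g)),
    "same-operon-genes" = .ref(function(kb, g, params)
      setdiff(.u(unlist(lapply(.geneOperons(kb, g),
                               function(o) slotValues(kb, o, "operon-genes")))),
              g)),
    "reactions" = .ref(function(kb, g, params) .geneReactions(kb, g)),
    "pathways" = .ref(function(kb, g, params) .genePathways(kb, g)),
    "go-terms" = .ref(function(kb, g, params)
      .u(slotValues(kb, g, "annotated-to"))),
    "promoters-regulated" = .ref(function(kb, g, params)
      .u(unlist(lapply(.geneUnits(kb, g), function(u)
        unlist(lapply(slotValues(kb, u, "binds-sites"),
                      function(s) slotValues(kb, s, "regulates-promoter"))))))),
    "complex-compression" = .ref(function(kb, g, params) {
      p <- slotValues(kb, g, "product")
      if (!length(p)) return(character(0))
      cx <- .u(unlist(lapply(p, function(x)
        slotValues(kb, x, "component-of"))))
      if (length(cx)) cx else .u(p)
    }),
    "coding-region" = list(output = "region", fn = function(kb, g, params) {
      r <- .geneRegion(kb, g)
      if (is.null(r)) list() else list(r)
    }),
    "promoter-flanks" = list(output = "sequence", fn = function(kb, g, params)
      .promoterFlankSeqs(kb, g, params$upstream %||% 50L,
                         params$downstream %||% 50L))
  ),
  Pathway = list(
    "reactions" = .ref(function(kb, p, params)
      .u(slotValues(kb, p, "reactions"))),
    "enzymes" = .ref(function(kb, p, params) .pathwayEnzymes(kb, p)),
    "genes" = .ref(function(kb, p, params)
      .u(unlist(lapply(.pathwayEnzymes(kb, p),
                       function(e) .enzymeGenes(kb, e))))),
    "metabolites" = .ref(function(kb, p, params) {
      mode <- .normMode(params)
      .u(unlist(lapply(slotValues(kb, p, "reactions"),
                       function(r) .rxnCompounds(kb, r, mode))))
    })
  ),
  Compound = list(
    "reactions" = .ref(function(kb, c, params)
      .compoundReactions(kb, c, .normMode(params))),
    "pathways" = .ref(function(kb, c, params)
      .u(unlist(lapply(.compoundReactions(kb, c, .normMode(params)),
                       function(r) slotValues(kb, r, "in-pathway"))))),
    "enzymes-activated" = .ref(function(kb, c, params)
      .u(slotValues(kb, c, "activates"))),
    "enzymes-inhibited" = .ref(function(kb, c, params)
      .u(slotValues(kb, c, "inhibits"))),
    "proteins-binding" = .ref(function(kb, c, params)
      .u(slotValues(kb, c, "ligand-of"))),
    "genes-regulated" = .ref(function(kb, c, params)
      .u(slotValues(kb, c, "tf-ligand-regulates")))
  ),
  Promoter = list(
    "binding-sites" = .ref(function(kb, p, params)
      .u(slotValues(kb, p, "binding-sites"))),
    "downstream-genes" = .ref(function(kb, p, params)
      .u(unlist(lapply(slotValues(kb, p, "controls"),
                       function(o) slotValues(kb, o, "operon-genes"))))),
    "region" = list(output = "region", fn = function(kb, p, params) {
      rep <- slotValues(kb, p, "replicon")
      if (!length(rep)) return(list())
      strand <- slotValues(kb, p, "strand")
      pos <- .slotNum(kb, p, "pos")
      list(seqRegion(rep[1], pos, pos,
                     if (length(strand)) strand[1] else "+"))
    })
  ),
  region = list(
    "length" = list(output = "number", fn = function(kb, r, params)
      as.numeric(r@end - r@start + 1L)),
    "nearest-gene" = list(output = "ref", fn = function(kb, r, params) {
      g <- nearestGene(kb, r)
      if (is.na(g)) character(0) else g
    }),
    "sequence" = list(output = "sequence", fn = function(kb, r, params)
      subsequence(kb, r)),
    "derive-region" = list(output = "region", fn = function(kb, r, params)
      list(deriveRegion(kb, r, params$offsetStart %||% 0L,
                        params$offsetEnd %||% 0L)))
  )
)

#' List the transformations applicable to a member class
#'
#' Different member classes offer different transformation menus; columns of
#' plain numbers or strings have no applicable transformations.
#'
#' @param classOrKind A frame class name or one of "number", "string",
#'   "region".
#' @return Character vector of transform names (possibly empty).
#' @export
applicableTransforms <- function(classOrKind) {
  reg <- .TRANSFORMS[[classOrKind]]
  if (is.null(reg)) character(0) else names(reg)
}

#' Add a transform column to a group
#'
#' Appends a column whose cell for each row is the deduplicated, id-ordered
#' result of the named transformation applied to that member. The column
#' records its transform name and parameters so it can be recomputed.
#'
#' @param g A [Group-class].
#' @param kb A [KnowledgeBase-class].
#' @param transform Transform name (see [applicableTransforms()]).
#' @param params Optional named list of parameters, e.g. `list(mode =
#'   "produced")` or `list(offsetStart = 100, offsetEnd = 100)`.
#' @return The [Group-class] with one more column.
#' @export
addTransformColumn <- function(g, kb, transform, params = list()) {
  .assertMutable(g)
  if (is.null(params)) params <- list()
  key <- g@memberClass
  reg <- .TRANSFORMS[[key]]
  def <- reg[[transform]]
  if (is.null(def)) {
    valid <- applicableTransforms(key)
    kgApplicabilityError(
      "transform '%s' not applicable to %s groups; valid: %s",
      transform, key,
      if (length(valid)) paste(valid, collapse = ", ") else "(none)")
  }
  cells <- lapply(g@members, function(m) def$fn(kb, m, params))
  header <- transform
  if (!is.null(params$mode)) header <- sprintf("%s (%s)", header, params$mode)
  g@columns <- c(g@columns,
                 .newColumn(header, "transform", def$output, cells,
                            spec = list(transform = transform,
                                        params = params)))
  validObject(g)
  g
}

#' Compress a gene group to its gene-product/complex set
#'
#' For each gene, if its product polypeptide forms one or more protein
#' complexes the complexes are taken, otherwise the polypeptide itself; the
#' results are pooled without redundancy, so e.g. eight genes encoding the
#' subunits of one complex compress to that single complex. Genes with no
#' product contribute nothing and are listed in the report
#' (`metadata(result)$report$noProduct`).
#'
#' @param g A [Group-class] of genes.
#' @param kb A [KnowledgeBase-class].
#' @return A [Group-class] of polypeptides and/or complexes (never larger
#'   than the input).
#' @export
compressToComplexes <- function(g, kb) {
  if (g@memberClass != "Gene")
    kgTypeError("complex compression needs a gene group")
  noProduct <- character(0)
  out <- character(0)
  for (gene in unlist(g@members, use.names = FALSE)) {
    v <- .TRANSFORMS$Gene[["complex-compression"]]$fn(kb, gene, list())
    if (!length(v)) noProduct <- c(noProduct, gene)
    out <- c(out, v)
  }
  out <- out[!duplicated(out)]
  cls <- unique(vapply(out, function(v) frameClass(kb, v), character(1)))
  res <- .newGroup(sprintf("complexes of %s", g@name),
                   if (length(cls) == 1) cls else "Frame", as.list(out),
                   metadata = list(report = list(noProduct = noProduct)))
  validObject(res)
  res
}

#' Derive a new region by offsetting an existing one
#'
#' The new region is `(start - offsetStart, end + offsetEnd)` on the same
#' replicon and strand, clamped to `[1, replicon length]`; e.g. offsets of
#' (100, 100) widen a region by 100 bp on each side. If the offsets invert
#' the region (start > end) a degenerate-region error is raised.
#'
#' @param kb A [KnowledgeBase-class].
#' @param region A [SeqRegion-class].
#' @param offsetStart Amount subtracted from the start (may be negative).
#' @param offsetEnd Amount added to the end (may be negative).
#' @return A [SeqRegion-class].
#' @export
deriveRegion <- function(kb, region, offsetStart, offsetEnd) {
  stopifnot(is(region, "SeqRegion"))
  len <- repliconLength(kb, region@replicon)
  st <- max(1L, min(len, region@start - as.integer(offsetStart)))
  en <- max(1L, min(len, region@end + as.integer(offsetEnd)))
  if (st > en)
    kgDegenerateRegionError(
      "offsets (%s, %s) invert region %d-%d (start %d > end %d)",
      offsetStart, offsetEnd, region@start, region@end, st, en)
  seqRegion(region@replicon, st, en, region@strand)
}

#' Nearest gene to a region
#'
#' Scans all genes on the region's replicon; distance is 0 for overlap,
#' otherwise the smallest gap between the region and the gene interval
#' (strand ignored). Ties break by lower gene start, then id.
#'
#' @param kb A [KnowledgeBase-class].
#' @param region A [SeqRegion-class].
#' @return A gene id, or `NA_character_` if the replicon has no genes.
#' @export
nearestGene <- function(kb, region) {
  best <- NA_character_; bestGap <- Inf; bestStart <- Inf
  for (g in frameIds(kb, "Gene")) {
    rep <- slotValues(kb, g, "replicon")
    if (!length(rep) || rep[1] != region@replicon) next
    st <- .slotNum(kb, g, "start"); en <- .slotNum(kb, g, "end")
    gap <- max(0, st - region@end, region@start - en)
    if (gap < bestGap || (gap == bestGap && st < bestStart)) {
      best <- g; bestGap <- gap; bestStart <- st
    }
  }
  best
}

# sequences of the promoter-proximal window(s) for one gene: promoter
# transcription start +/- the given distances, strand-aware (upstream means
# 5' of the promoter on its own strand)
.promoterFlankSeqs <- function(kb, g, upstream, downstream) {
  proms <- .genePromoters(kb, g)
  out <- character(0)
  for (p in proms) {
    rep <- slotValues(kb, p, "replicon")
    if (!length(rep)) next
    len <- repliconLength(kb, rep[1])
    pos <- .slotNum(kb, p, "pos")
    strand <- slotValues(kb, p, "strand")
    strand <- if (length(strand)) strand[1] else "+"
    if (strand == "+") { st <- pos - upstream; en <- pos + downstream }
    else { st <- pos - downstream; en <- pos + upstream }
    st <- max(1, st); en <- min(len, en)
    out <- c(out, subsequence(kb, seqRegion(rep[1], st, en, strand)))
  }
  unique(out)
}

#' Extract promoter-flanking sequences for a gene group
#'
#' Appends a sequence column: for each gene, the nucleotide sequence from
#' `upstream` bases before to `downstream` bases after the transcription
#' start of the gene's promoter (found via its operon), respecting the
#' promoter strand. Genes without a promoter get empty cells; windows are
#' clamped to the replicon.
#'
#' @param g A [Group-class] of genes.
#' @param kb A [KnowledgeBase-class].
#' @param upstream,downstream Non-negative distances in bp (default 50).
#' @return The [Group-class] with one more (sequence) column.
#' @export
promoterFlanks <- function(g, kb, upstream = 50L, downstream = 50L) {
  if (g@memberClass != "Gene")
    kgTypeError("promoter flanks need a gene group")
  if (upstream < 0 || downstream < 0)
    kgArgumentError("distances must be >= 0")
  addTransformColumn(g, kb, "promoter-flanks",
                     params = list(upstream = as.integer(upstream),
                                   downstream = as.integer(downstream)))
}
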