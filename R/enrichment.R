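# Enrichment analysis: Fisher exact upper tail, parent-child union and
# intersection variants, multiple-testing correction, and the category
# sources (GO ontologies, pathways + pathway classes, transcriptional
# regulators, metabolite pathways, combined).

#' One-sided Fisher exact (hypergeometric upper tail) probability
#'
#' Probability of observing `k` or more category members in a draw of `n`
#' objects from a population of `N` containing `K` category members:
#' `P(X >= k) = sum_{i=k}^{min(n,K)} C(K,i) C(N-K,n-i) / C(N,n)`. Computed
#' in log space (`lchoose` + log-sum-exp) for numerical safety.
#'
#' @param k,n,K,N Non-negative integers with `k <= n <= N` and
#'   `k <= K <= N`.
#' @return A probability in (0, 1].
#' @export
fisherTail <- function(k, n, K, N) {
  v <- c(k = k, n = n, K = K, N = N)
  if (any(v < 0) || any(v != round(v)))
    kgArgumentError("k, n, K, N must be non-negative integers")
  if (n > N || K > N || k > n || k > K)
    kgArgumentError("need k <= n <= N and k <= K <= N (got k=%d n=%d K=%d N=%d)",
                    k, n, K, N)
  if (k == 0) return(1)
  i <- k:min(n, K)
  lt <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  m <- max(lt)
  min(1, exp(m) * sum(exp(lt - m)))
}

# ---- GO annotation propagation (true-path rule) --------------------------

.goAncestors <- function(kb, term, memo = new.env(parent = emptyenv())) {
  if (!is.null(memo[[term]])) return(memo[[term]])
  parents <- slotValues(kb, term, "is-a")
  anc <- parents
  for (p in parents) anc <- c(anc, .goAncestors(kb, p, memo))
  memo[[term]] <- unique(anc)
  memo[[term]]
}

#' Propagated GO annotation sets
#'
#' Applies the true-path rule: a gene annotated to a term is implicitly
#' annotated to every ancestor of that term. Returns, for every GO term of
#' the requested ontology, the full set of annotated genes.
#'
#' @param kb A [KnowledgeBase-class].
#' @param ontology One of "molecular-function", "biological-process",
#'   "cellular-location", or `NULL` for all terms.
#' @return Named list: term id -> character vector of gene ids.
#' @export
goAnnotations <- function(kb, ontology = NULL) {
  terms <- frameIds(kb, "GOTerm")
  if (!is.null(ontology))
    terms <- terms[vapply(terms, function(t)
      identical(slotValues(kb, t, "ontology"), ontology), logical(1))]
  anno <- stats::setNames(
    lapply(terms, function(t) slotValues(kb, t, "annotates")), terms)
  memo <- new.env(parent = emptyenv())
  allTerms <- frameIds(kb, "GOTerm")
  for (t in allTerms) {
    direct <- slotValues(kb, t, "annotates")
    if (!length(direct)) next
    for (a in intersect(.goAncestors(kb, t, memo), terms))
      anno[[a]] <- c(anno[[a]], direct)
  }
  lapply(anno, function(x) sort(unique(x)))
}

#' Parent-child enrichment probabilities
#'
#' Fisher exact variants that condition a GO term's test on the genes
#' annotated to its parents: the population is restricted to the genes
#' annotated (after true-path propagation) to the union
#' (`pcUnionP`) or intersection (`pcIntersectionP`) of the term's parents.
#' Within that restricted population the usual upper-tail test is applied
#' with `K' = |anno(term)|`, `n' = |group` in the restricted population`|`
#' and `k = |group` in `anno(term)|`.
#'
#' @param kb A [KnowledgeBase-class].
#' @param term A GO term id with at least one parent.
#' @param groupIds Character vector of gene ids (the group).
#' @param anno Optional precomputed propagated annotations
#'   ([goAnnotations()] for the term's ontology).
#' @return A probability in (0, 1].
#' @export
pcUnionP <- function(kb, term, groupIds, anno = NULL) {
  .pcP(kb, term, groupIds, anno, union = TRUE)
}

#' @rdname pcUnionP
#' @export
pcIntersectionP <- function(kb, term, groupIds, anno = NULL) {
  .pcP(kb, term, groupIds, anno, union = FALSE)
}

.pcP <- function(kb, term, groupIds, anno, union) {
  parents <- slotValues(kb, term, "is-a")
  if (!length(parents))
    kgApplicabilityError("term '%s' has no parents; parent-child test undefined",
                         term)
  if (is.null(anno))
    anno <- goAnnotations(kb, slotValues(kb, term, "ontology"))
  psets <- lapply(parents, function(p) anno[[p]] %||% character(0))
  pop <- if (union) unique(unlist(psets)) else Reduce(intersect, psets)
  if (!length(pop))
    kgApplicabilityError("empty restricted population for term '%s'", term)
  termSet <- intersect(anno[[term]] %||% character(0), pop)
  grp <- intersect(unique(groupIds), pop)
  fisherTail(length(intersect(grp, termSet)), length(grp),
             length(termSet), length(pop))
}

#' Multiple-testing correction
#'
#' Adjusts raw p-values by Bonferroni (`min(1, m p)`), Benjamini-Hochberg
#' (step-up FDR) or Benjamini-Yekutieli (BH with the `sum(1/i)` factor,
#' valid under arbitrary dependence). Output order matches input order.
#'
#' @param p Numeric vector of probabilities in \[0, 1\].
#' @param method "bonferroni", "bh" or "by".
#' @return Numeric vector of adjusted probabilities.
#' @export
adjustPvalues <- function(p, method = c("bh", "bonferroni", "by")) {
  method <- match.arg(tolower(method[1]), c("bh", "bonferroni", "by"))
  if (any(is.na(p)) || any(p < 0 | p > 1))
    kgArgumentError("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = c(bh = "BH", bonferroni = "bonferroni",
                                by = "BY")[[method]])
}

# ---- category sources ----------------------------------------------------

# regulon of a regulator protein: direct regulates slot unioned with the
# binding-site -> promoter -> operon chain
.regulonOf <- function(kb, prot) {
  chain <- unlist(lapply(slotValues(kb, prot, "binds-sites"), function(s)
    unlist(lapply(slotValues(kb, s, "regulates-promoter"), function(pm)
      unlist(lapply(slotValues(kb, pm, "controls"), function(o)
        slotValues(kb, o, "operon-genes")))))))
  sort(unique(c(slotValues(kb, prot, "regulates"), chain)))
}

# descendant pathways of a pathway class (inclusive of direct ones)
.classPathways <- function(kb, pc) {
  own <- slotValues(kb, pc, "class-pathways")
  subs <- slotValues(kb, pc, "sub-classes")
  sort(unique(c(own, unlist(lapply(subs, function(s) .classPathways(kb, s))))))
}

.pathwayGeneSets <- function(kb) {
  pw <- frameIds(kb, "Pathway")
  sets <- stats::setNames(lapply(pw, function(p)
    .TRANSFORMS$Pathway$genes$fn(kb, p, list())), pw)
  for (pc in frameIds(kb, "PathwayClass"))
    sets[[pc]] <- sort(unique(unlist(sets[.classPathways(kb, pc)])))
  sets
}

.pathwaySubstrateSets <- function(kb) {
  pw <- frameIds(kb, "Pathway")
  sets <- stats::setNames(lapply(pw, function(p)
    .TRANSFORMS$Pathway$metabolites$fn(kb, p, list(mode = "both"))), pw)
  for (pc in frameIds(kb, "PathwayClass"))
    sets[[pc]] <- sort(unique(unlist(sets[.classPathways(kb, pc)])))
  sets
}

.regulatorGeneSets <- function(kb) {
  sets <- list()
  for (prot in c(frameIds(kb, "Polypeptide"), frameIds(kb, "ProteinComplex"))) {
    regulon <- .regulonOf(kb, prot)
    if (!length(regulon)) next
    genes <- .enzymeGenes(kb, prot)   # encoding gene(s)
    for (g in genes) sets[[g]] <- sort(unique(c(sets[[g]], regulon)))
  }
  sets
}

.ONT_OF_SOURCE <- c(go_mf = "molecular-function", go_bp = "biological-process",
                    go_cc = "cellular-location")

.categorySets <- function(kb, source) {
  if (source %in% names(.ONT_OF_SOURCE))
    return(goAnnotations(kb, .ONT_OF_SOURCE[[source]]))
  switch(source,
         pathways = .pathwayGeneSets(kb),
         regulators = .regulatorGeneSets(kb),
         compound_pathways = .pathwaySubstrateSets(kb),
         combined = c(goAnnotations(kb, "molecular-function"),
                      goAnnotations(kb, "biological-process"),
                      goAnnotations(kb, "cellular-location"),
                      .pathwayGeneSets(kb), .regulatorGeneSets(kb)),
         kgArgumentError("unknown category source '%s'", source))
}

#' Enrichment analysis of a group
#'
#' Tests whether categories (GO terms of one ontology, pathways and pathway
#' classes, transcriptional regulators keyed by their gene, or — for
#' compound groups — pathways containing the compounds as substrates) are
#' over-represented in the group relative to a background population, which
#' defaults to all KB frames of the group's member class. Each category with
#' at least one group member is tested; the correction is applied across all
#' tested categories of the analysis (for `combined`, across the pooled GO +
#' pathway + regulator category set); categories with adjusted p below
#' `threshold` are returned as a group sorted by adjusted p, carrying k, K,
#' p columns and the supporting members. Parent-child tests are only defined
#' for the GO sources; root terms (no parents) and categories with an empty
#' restricted population are skipped and listed in
#' `metadata(result)$skipped`.
#'
#' @param g A [Group-class] (genes for all sources except
#'   `compound_pathways`, which takes compounds).
#' @param kb A [KnowledgeBase-class].
#' @param source One of "go_mf", "go_bp", "go_cc", "pathways", "regulators",
#'   "compound_pathways", "combined".
#' @param test One of "fisher", "pc_union", "pc_intersection".
#' @param correction One of "bh", "bonferroni", "by".
#' @param threshold Report categories with adjusted p at or below this
#'   value (in (0, 1]; 1 returns every tested category).
#' @param background Optional [Group-class] supplying a custom background
#'   population.
#' @return A [Group-class] of enriched categories;
#'   `metadata(result)$enrichment` holds the full result table
#'   (see [enrichTable()]).
#' @export
enrich <- function(g, kb,
                   source = c("pathways", "go_mf", "go_bp", "go_cc",
                              "regulators", "compound_pathways", "combined"),
                   test = c("fisher", "pc_union", "pc_intersection"),
                   correction = c("bh", "bonferroni", "by"),
                   threshold = 0.05, background = NULL) {
  source <- match.arg(source)
  test <- match.arg(test)
  correction <- match.arg(correction)
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1)
    kgArgumentError("threshold must lie in (0, 1]")
  popClass <- if (source == "compound_pathways") "Compound" else "Gene"
  if (g@memberClass != popClass)
    kgTypeError("source '%s' needs a %s group", source, popClass)
  if (test != "fisher" && !source %in% names(.ONT_OF_SOURCE))
    kgApplicabilityError(
      "parent-child tests need a DAG-structured (GO) source, not '%s'", source)

  pop <- if (is.null(background)) frameIds(kb, popClass)
    else unlist(background@members, use.names = FALSE)
  grp <- intersect(unlist(g@members, use.names = FALSE), pop)
  n <- length(grp); N <- length(pop)

  sets <- lapply(.categorySets(kb, source), function(s) intersect(s, pop))
  sets <- sets[vapply(sets, length, integer(1)) > 0]
  supp <- lapply(sets, function(s) intersect(grp, s))
  tested <- names(sets)[vapply(supp, length, integer(1)) > 0]

  skipped <- character(0)
  pRaw <- numeric(0)
  for (cat in tested) {
    p <- if (test == "fisher") {
      fisherTail(length(supp[[cat]]), n, length(sets[[cat]]), N)
    } else {
      anno <- sets  # already propagated + restricted to pop
      tryCatch(
        .pcP(kb, cat, grp, anno, union = (test == "pc_union")),
        kgApplicabilityError = function(e) NA_real_)
    }
    if (is.na(p)) { skipped <- c(skipped, cat); next }
    pRaw[cat] <- p
  }
  pAdj <- if (length(pRaw)) adjustPvalues(unname(pRaw), correction) else numeric(0)
  names(pAdj) <- names(pRaw)

  tab <- data.frame(category = names(pRaw),
                    k = vapply(names(pRaw), function(c) length(supp[[c]]),
                               integer(1)),
                    n = n,
                    K = vapply(names(pRaw), function(c) length(sets[[c]]),
                               integer(1)),
                    N = N, p_raw = unname(pRaw), p_adj = unname(pAdj),
                    row.names = NULL, stringsAsFactors = FALSE)
  ord <- order(tab$p_adj, tab$p_raw, tab$category)
  tab <- tab[ord, , drop = FALSE]
  hits <- tab[tab$p_adj <= threshold, , drop = FALSE]

  cls <- unique(vapply(hits$category, function(c) frameClass(kb, c),
                       character(1)))
  res <- .newGroup(sprintf("%s enrichment of %s", source, g@name),
                   if (length(cls) == 1) cls else "Frame",
                   as.list(hits$category))
  num <- function(h, v) .newColumn(h, "stored", "number", as.list(v))
  res@columns <- list(
    num("k", as.numeric(hits$k)), num("K", as.numeric(hits$K)),
    num("p-raw", hits$p_raw), num("p-adj", hits$p_adj),
    .newColumn("members", "stored", "ref",
               lapply(hits$category, function(c) sort(supp[[c]]))))
  res@metadata <- list(enrichment = tab, source = source, test = test,
                       correction = correction, threshold = threshold,
                       skipped = skipped)
  validObject(res)
  res
}

#' Full result table of an enrichment analysis
#'
#' @param g The [Group-class] returned by [enrich()].
#' @return `data.frame` with columns category, k, n, K, N, p_raw, p_adj for
#'   every tested category (not only those under the threshold).
#' @export
enrichTable <- function(g) {
  tab <- g@metadata$enrichment
  if (is.null(tab)) kgArgumentError("group carries no enrichment results")
  tab
}

#' Group metadata
#'
#' @param g A [Group-class].
#' @return The free-form metadata list (import reports, enrichment tables,
#'   compression reports).
#' @export
groupMetadata <- function(g) g@metadata
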