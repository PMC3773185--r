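# Deterministic synthetic pathway/genome knowledge-base generator.

# run expr with a fixed RNG seed, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# fill in missing inverse slot values for every ref slot; sort + dedupe all
# ref slots so generated KBs are canonical
.withInverses <- function(frames) {
  names(frames) <- vapply(frames, function(f) f$id, character(1))
  for (id in names(frames)) {
    f <- frames[[id]]
    for (s in names(f$slots)) {
      def <- .slotDef(s)
      if (is.null(def) || def$kind != "ref") next
      for (v in f$slots[[s]]) {
        if (is.null(frames[[v]]))
          kgIntegrityError("dangling reference '%s' in %s.%s", v, id, s)
        inv <- def$inverse
        frames[[v]]$slots[[inv]] <- c(frames[[v]]$slots[[inv]], id)
      }
    }
  }
  for (id in names(frames)) {
    for (s in names(frames[[id]]$slots)) {
      def <- .slotDef(s)
      if (!is.null(def) && def$kind == "ref")
        frames[[id]]$slots[[s]] <- sort(unique(frames[[id]]$slots[[s]]))
    }
  }
  frames
}

.fr <- function(id, class, name = id, synonyms = character(0), ...) {
  slots <- list(...)
  slots <- slots[vapply(slots, length, integer(1)) > 0]
  slots <- lapply(slots, as.character)
  names(slots) <- gsub("_", "-", names(slots))
  list(id = id, class = class, name = name, synonyms = synonyms, slots = slots)
}

#' Generate a synthetic pathway/genome knowledge base
#'
#' Builds a complete, internally consistent toy organism: a random genome
#' with non-overlapping genes grouped into operons (one promoter each, with
#' zero or more regulator binding sites), regulator proteins (one tagged as a
#' sigma factor) each controlling at least one operon, enzymes (monomeric
#' polypeptides and multi-subunit complexes) catalysing reactions over
#' compound substrates, pathways of reactions arranged under a pathway-class
#' tree, and a three-ontology GO DAG with leaf-level gene annotations. The
#' result is deterministic for a given `(seed, sizes)` and always passes
#' [validateKb()].
#'
#' @param seed Integer RNG seed.
#' @param sizes Named list overriding any of the default counts:
#'   `genes` (120), `operons` (40), `regulators` (8), `complexes` (6),
#'   `pathways` (12), `pathwayClasses` (3), `reactions` (36),
#'   `compounds` (40), `goMid` (4), `goLeaves` (8), `geneLength` (300),
#'   `intergenic` (200).
#' @return A validated [KnowledgeBase-class].
#' @export
generateToyPgdb <- function(seed = 1L, sizes = list()) {
  sz <- list(genes = 120L, operons = 40L, regulators = 8L, complexes = 6L,
             pathways = 12L, pathwayClasses = 3L, reactions = 36L,
             compounds = 40L, goMid = 4L, goLeaves = 8L,
             geneLength = 300L, intergenic = 200L)
  unknown <- setdiff(names(sizes), names(sz))
  if (length(unknown)) kgConfigError("unknown size parameter(s): %s",
                                     paste(unknown, collapse = ", "))
  sz[names(sizes)] <- lapply(sizes, as.integer)
  if (any(vapply(sz, function(x) is.na(x) || x < 1L, logical(1))))
    kgConfigError("all size parameters must be positive integers")
  if (sz$operons > sz$genes)
    kgConfigError("more operons (%d) than genes (%d)", sz$operons, sz$genes)
  if (sz$regulators + 4L * sz$complexes > sz$genes)
    kgConfigError("genes (%d) cannot host %d regulators plus %d complexes",
                  sz$genes, sz$regulators, sz$complexes)
  if (sz$reactions < sz$pathways)
    kgConfigError("fewer reactions (%d) than pathways (%d)",
                  sz$reactions, sz$pathways)
  if (sz$compounds < 4L) kgConfigError("need at least 4 compounds")

  .withSeed(seed, .buildToyPgdb(sz))
}

.buildToyPgdb <- function(sz) {
  gid <- sprintf("g%03d", seq_len(sz$genes))
  pid <- sprintf("pp-%s", gid)          # polypeptide of each gene
  names(pid) <- gid

  # --- operon membership: every operon gets >=1 gene ----------------------
  opOf <- integer(sz$genes)
  opOf[seq_len(sz$operons)] <- seq_len(sz$operons)
  if (sz$genes > sz$operons)
    opOf[(sz$operons + 1L):sz$genes] <-
      sample(sz$operons, sz$genes - sz$operons, replace = TRUE)
  # shuffle which gene ids land in which operon slot
  opOf <- opOf[sample(sz$genes)]

  # --- genome layout ------------------------------------------------------
  frames <- list()
  cursor <- 300L
  located <- character(0)
  geneRows <- list()
  opStrand <- character(sz$operons)
  promPos <- integer(sz$operons)
  for (o in seq_len(sz$operons)) {
    og <- gid[opOf == o]
    strand <- sample(c("+", "-"), 1L)
    opStrand[o] <- strand
    blockStart <- cursor
    for (g in og) {
      st <- cursor; en <- cursor + sz$geneLength - 1L
      geneRows[[g]] <- list(start = st, end = en, strand = strand)
      cursor <- en + 51L
    }
    blockEnd <- cursor - 51L
    promPos[o] <- if (strand == "+") blockStart - 60L else blockEnd + 60L
    cursor <- cursor + sz$intergenic
  }
  genomeLen <- cursor + 300L
  stopifnot(all(promPos >= 1L & promPos <= genomeLen))

  # --- gene roles: regulators, complex subunits, plain enzymes ------------
  shuffled <- sample(gid)
  regGenes <- shuffled[seq_len(sz$regulators)]
  pool <- shuffled[-seq_len(sz$regulators)]
  complexMembers <- list()
  for (k in seq_len(sz$complexes)) {
    ksz <- sample(2:4, 1L)
    complexMembers[[k]] <- pool[seq_len(ksz)]
    pool <- pool[-seq_len(ksz)]
  }
  cplxIds <- sprintf("cplx-%02d", seq_len(sz$complexes))
  regProts <- pid[regGenes]

  # --- regulation: each regulator targets 1-3 operons ---------------------
  siteRows <- list()   # per operon: list of regulator proteins
  regTargets <- list()
  for (r in seq_along(regProts)) {
    nops <- sample(1:3, 1L)
    regTargets[[r]] <- sample(sz$operons, min(nops, sz$operons))
    for (o in regTargets[[r]])
      siteRows[[length(siteRows) + 1L]] <-
        list(op = o, prot = regProts[[r]], n = length(siteRows) + 1L)
  }

  # --- reactions, compounds, enzymes, pathways ----------------------------
  cid <- sprintf("c%03d", seq_len(sz$compounds))
  rid <- sprintf("rxn-%03d", seq_len(sz$reactions))
  monomers <- pid[setdiff(gid, c(regGenes, unlist(complexMembers)))]
  rxnDef <- list()
  for (i in seq_len(sz$reactions)) {
    cc <- sample(cid, sample(2:4, 1L))
    nl <- sample(seq_len(length(cc) - 1L), 1L)
    enz <- character(0)
    if (i <= sz$complexes) enz <- cplxIds[i]
    enz <- c(enz, sample(monomers, sample(1:2, 1L)))
    rxnDef[[i]] <- list(left = cc[seq_len(nl)], right = cc[-seq_len(nl)],
                        dir = sample(c("L2R", "L2R", "L2R", "R2L", "REV"), 1L),
                        enz = enz)
  }
  pwyOf <- rep(seq_len(sz$pathways), length.out = sz$reactions)
  pwyIds <- sprintf("pwy-%02d", seq_len(sz$pathways))
  pcIds <- sprintf("pc-%02d", seq_len(sz$pathwayClasses))
  pcOf <- rep(seq_len(sz$pathwayClasses), length.out = sz$pathways)

  # --- GO DAG -------------------------------------------------------------
  goFrames <- list()
  goLeafIds <- list()
  for (o in .GO_ONTOLOGIES) {
    code <- c("molecular-function" = "mf", "biological-process" = "bp",
              "cellular-location" = "cc")[[o]]
    root <- sprintf("go-%s-root", code)
    goFrames[[root]] <- .fr(root, "GOTerm", name = paste(o, "root"),
                            ontology = o)
    mids <- sprintf("go-%s-m%d", code, seq_len(sz$goMid))
    for (m in mids)
      goFrames[[m]] <- .fr(m, "GOTerm", ontology = o, is_a = root)
    leaves <- sprintf("go-%s-l%d", code, seq_len(sz$goLeaves))
    for (l in leaves)
      goFrames[[l]] <- .fr(l, "GOTerm", ontology = o,
                           is_a = sample(mids, sample(1:2, 1L)))
    goLeafIds[[o]] <- leaves
  }

  # --- assemble frames ----------------------------------------------------
  add <- function(f) frames[[length(frames) + 1L]] <<- f

  add(.fr("org-1", "Organism", name = "Toyella synthetica", genome = "CHR1"))
  add(.fr("CHR1", "Replicon", name = "chromosome 1", organism = "org-1"))

  for (g in gid) {
    anno <- unlist(lapply(.GO_ONTOLOGIES, function(o)
      sample(goLeafIds[[o]], sample(1:2, 1L))))
    gr <- geneRows[[g]]
    add(.fr(g, "Gene", name = g, synonyms = sprintf("syn-%s", g),
            product = pid[[g]], replicon = "CHR1",
            start = gr$start, end = gr$end, strand = gr$strand,
            annotated_to = anno))
    located <- c(located, g)
  }
  for (g in gid) {
    comp <- character(0)
    for (k in seq_len(sz$complexes))
      if (g %in% complexMembers[[k]]) comp <- c(comp, cplxIds[k])
    add(.fr(pid[[g]], "Polypeptide", name = sprintf("%s protein", g),
            gene = g, component_of = comp))
  }
  for (k in seq_len(sz$complexes))
    add(.fr(cplxIds[k], "ProteinComplex",
            name = sprintf("complex %02d", k),
            components = pid[complexMembers[[k]]]))

  for (o in seq_len(sz$operons)) {
    opId <- sprintf("op-%02d", o)
    pmId <- sprintf("pm-%02d", o)
    add(.fr(opId, "Operon", operon_genes = gid[opOf == o], promoter = pmId))
    add(.fr(pmId, "Promoter", controls = opId, replicon = "CHR1",
            pos = promPos[o], strand = opStrand[o]))
    located <- c(located, pmId)
  }
  for (s in siteRows) {
    bsId <- sprintf("bs-%03d", s$n)
    pm <- promPos[s$op]
    if (opStrand[s$op] == "+") { st <- pm - 25L; en <- pm - 16L }
    else { st <- pm + 16L; en <- pm + 25L }
    add(.fr(bsId, "BindingSite", bound_by = s$prot,
            regulates_promoter = sprintf("pm-%02d", s$op),
            replicon = "CHR1", start = st, end = en,
            strand = opStrand[s$op]))
    located <- c(located, bsId)
  }

  for (i in seq_len(sz$reactions)) {
    d <- rxnDef[[i]]
    add(.fr(rid[i], "Reaction", left = d$left, right = d$right,
            direction = d$dir, enzymes = d$enz,
            in_pathway = pwyIds[pwyOf[i]]))
  }
  for (c in cid) add(.fr(c, "Compound", name = sprintf("compound %s", c)))
  for (p in seq_len(sz$pathways))
    add(.fr(pwyIds[p], "Pathway", name = sprintf("pathway %02d", p),
            in_class = pcIds[pcOf[p]]))
  add(.fr("pc-root", "PathwayClass", name = "Pathways"))
  for (k in seq_len(sz$pathwayClasses))
    add(.fr(pcIds[k], "PathwayClass", name = sprintf("pathway class %02d", k),
            parent_class = "pc-root"))
  for (f in goFrames) add(f)

  # regulator proteins: sigma tag + materialised regulates slot
  names(frames) <- vapply(frames, function(f) f$id, character(1))
  for (r in seq_along(regProts)) {
    prot <- regProts[[r]]
    frames[[prot]]$slots[["sigma-factor"]] <-
      if (r == 1L) "true" else "false"
    frames[[prot]]$slots[["regulates"]] <-
      unlist(lapply(regTargets[[r]], function(o) gid[opOf == o]))
  }
  frames[["CHR1"]]$slots[["features"]] <- located

  seq <- paste(sample(c("A", "C", "G", "T"), genomeLen, replace = TRUE),
               collapse = "")
  seqs <- Biostrings::DNAStringSet(seq)
  names(seqs) <- "CHR1"

  kb <- .newKb(.withInverses(frames), seqs)
  validateKb(kb)
  kb
}

#' Path to the bundled minitoy knowledge base
#'
#' A small fixed fixture: 8 `atp` genes whose products form the ATPSYN-F1
#' complex, 3 further genes (`g1`-`g3`) catalysing the two reactions of
#' pathway `PWY-1`, regulator crpX acting on `g1`/`g2` through promoter
#' `pm1`/binding site `bs1`, compounds, and GO annotations.
#'
#' @return File path suitable for [loadKb()].
#' @export
minitoyPath <- function() {
  system.file("extdata", "minitoy.kb", package = "kgroups", mustWork = TRUE)
}
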