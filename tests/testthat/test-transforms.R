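# transforms: applicability rules, the per-class transform families,
# complex compression, regions, promoter flanks.

test_that("transform menus depend on the member datatype", {
  expect_true(all(c("regulators", "regulated-genes", "binding-sites",
                    "promoters", "operons", "same-operon-genes", "reactions",
                    "pathways", "go-terms", "complex-compression",
                    "coding-region") %in% applicableTransforms("Gene")))
  expect_identical(applicableTransforms("number"), character(0))
  expect_identical(applicableTransforms("string"), character(0))
  expect_length(applicableTransforms("Pathway"), 4)
  expect_setequal(applicableTransforms("Pathway"),
                  c("reactions", "enzymes", "genes", "metabolites"))
})

test_that("inapplicable transforms raise an error naming valid options", {
  kb <- miniKb()
  g <- createGroup(kb, "c", "cpd-A", "Compound")
  err <- tryCatch(addTransformColumn(g, kb, "regulators"),
                  kgApplicabilityError = identity)
  expect_s3_class(err, "kgApplicabilityError")
  expect_match(conditionMessage(err), "enzymes-activated")
})

test_that("gene transforms traverse the regulation and metabolic relations", {
  kb <- miniKb()
  g <- createGroup(kb, "g12", c("g1", "g2"), "Gene")
  g <- addTransformColumn(g, kb, "regulators")
  expect_identical(columnCells(g, 2), list("CRPX", "CRPX"))

  atp <- createGroup(kb, "atpA", "atpA", "Gene")
  atp <- addTransformColumn(atp, kb, "pathways")
  expect_identical(columnCells(atp, 2)[[1]], character(0))

  g1 <- createGroup(kb, "g1", "g1", "Gene")
  for (tr in c("promoters", "operons", "binding-sites", "same-operon-genes",
               "reactions", "pathways", "go-terms", "promoters-regulated",
               "regulated-genes")) {
    g1 <- addTransformColumn(g1, kb, tr)
  }
  cells <- lapply(2:10, function(i) columnCells(g1, i)[[1]])
  expect_identical(cells[[1]], "pm1")
  expect_identical(cells[[2]], "op1")
  expect_identical(cells[[3]], "bs1")
  expect_identical(cells[[4]], "g2")          # sibling, self excluded
  expect_identical(cells[[5]], "rxn1")
  expect_identical(cells[[6]], "PWY-1")
  expect_identical(cells[[7]], c("GO-BP-1", "GO-MF-2"))
  expect_identical(cells[[8]], character(0))  # PP-G1 binds no sites
  expect_identical(cells[[9]], character(0))  # PP-G1 regulates nothing

  cr <- addTransformColumn(g1, kb, "coding-region")
  reg <- columnCells(cr, 11)[[1]][[1]]
  expect_equal(c(reg@start, reg@end), c(1601, 1900))
})

test_that("pathway transforms cover reactions, enzymes, genes, metabolites", {
  kb <- miniKb()
  p <- createGroup(kb, "p", "PWY-1", "Pathway")
  p <- addTransformColumn(p, kb, "reactions")
  p <- addTransformColumn(p, kb, "enzymes")
  p <- addTransformColumn(p, kb, "genes")
  expect_identical(columnCells(p, 2)[[1]], c("rxn1", "rxn2"))
  expect_identical(columnCells(p, 3)[[1]], c("PP-G1", "PP-G2", "PP-G3"))
  expect_identical(columnCells(p, 4)[[1]], c("g1", "g2", "g3"))
  met <- function(mode) {
    q <- addTransformColumn(createGroup(kb, "p", "PWY-1", "Pathway"), kb,
                            "metabolites", params = list(mode = mode))
    columnCells(q, 2)[[1]]
  }
  # rxn1 (L2R): cpd-A -> cpd-B; rxn2 (REV): cpd-B <-> cpd-C
  expect_identical(met("produced"), c("cpd-B", "cpd-C"))
  expect_identical(met("consumed"), c("cpd-A", "cpd-B", "cpd-C"))
  expect_identical(met("both"), c("cpd-A", "cpd-B", "cpd-C"))
})

test_that("compound transforms respect reaction direction and regulation", {
  kb <- miniKb()
  tr <- function(id, name, mode = NULL) {
    g <- createGroup(kb, "c", id, "Compound")
    g <- addTransformColumn(g, kb, name,
                            params = if (is.null(mode)) list()
                                     else list(mode = mode))
    columnCells(g, 2)[[1]]
  }
  expect_identical(tr("cpd-B", "reactions", "producing"), c("rxn1", "rxn2"))
  expect_identical(tr("cpd-B", "reactions", "consuming"), "rxn2")
  expect_identical(tr("cpd-A", "reactions", "consuming"), "rxn1")
  expect_identical(tr("cpd-A", "reactions", "producing"), character(0))
  expect_identical(tr("cpd-B", "pathways", "both"), "PWY-1")
  expect_identical(tr("cpd-D", "enzymes-activated"), "PP-G1")
  expect_identical(tr("cpd-D", "enzymes-inhibited"), "PP-G3")
  expect_identical(tr("cpd-D", "proteins-binding"), "CRPX")
  expect_identical(tr("cpd-D", "genes-regulated"), c("g1", "g2"))
})

test_that("promoter transforms find sites, downstream genes and the region", {
  kb <- miniKb()
  p <- createGroup(kb, "pm", "pm1", "Promoter")
  p <- addTransformColumn(p, kb, "binding-sites")
  p <- addTransformColumn(p, kb, "downstream-genes")
  p <- addTransformColumn(p, kb, "region")
  expect_identical(columnCells(p, 2)[[1]], "bs1")
  expect_identical(columnCells(p, 3)[[1]], c("g1", "g2"))
  reg <- columnCells(p, 4)[[1]][[1]]
  expect_equal(c(reg@start, reg@end), c(1560, 1560))
})

test_that("region transforms compute length, sequence and derived regions", {
  kb <- miniKb()
  r <- seqRegion("CHR1", 500, 900, "+")
  g <- createGroup(kb, "r", list(r), "region")
  g <- addTransformColumn(g, kb, "length")
  expect_identical(columnCells(g, 2)[[1]], 401)
  g <- addTransformColumn(g, kb, "sequence")
  expect_identical(columnCells(g, 3)[[1]],
                   subsequence(kb, r))
  g <- addTransformColumn(g, kb, "derive-region",
                          params = list(offsetStart = 100, offsetEnd = 100))
  d <- columnCells(g, 4)[[1]][[1]]
  expect_equal(c(d@start, d@end), c(400, 1000))
})

test_that("deriveRegion clamps to the replicon and rejects inversion", {
  kb <- miniKb()
  d <- deriveRegion(kb, seqRegion("CHR1", 50, 80), 100, 0)
  expect_equal(c(d@start, d@end), c(1, 80))
  d2 <- deriveRegion(kb, seqRegion("CHR1", 2900, 2990), 0, 100)
  expect_equal(d2@end, 3000)
  expect_error(deriveRegion(kb, seqRegion("CHR1", 10, 20), -50, -50),
               class = "kgDegenerateRegionError")
})

test_that("nearest gene agrees with an independent scan", {
  kb <- genKb()
  genes <- frameIds(kb, "Gene")
  starts <- vapply(genes, function(g) kgroups:::.slotNum(kb, g, "start"),
                   numeric(1))
  ends <- vapply(genes, function(g) kgroups:::.slotNum(kb, g, "end"),
                 numeric(1))
  oracle <- function(r) {
    gap <- pmax(0, starts - r@end, r@start - ends)
    cand <- which(gap == min(gap))
    cand <- cand[order(starts[cand], genes[cand])]
    unname(genes[cand[1]])
  }
  set.seed(11)
  len <- repliconLength(kb, "CHR1")
  for (i in 1:25) {
    a <- sample(len - 200, 1)
    r <- seqRegion("CHR1", a, a + sample(5:200, 1))
    expect_identical(nearestGene(kb, r), oracle(r))
  }
  # minitoy: a region inside g1 maps to g1
  expect_identical(nearestGene(miniKb(), seqRegion("CHR1", 1700, 1750)), "g1")
})

test_that("complex compression collapses shared complexes", {
  kb <- miniKb()
  atp <- createGroup(kb, "atp", sprintf("atp%s", LETTERS[1:8]), "Gene")
  cg <- compressToComplexes(atp, kb)
  expect_identical(memberIds(cg), "ATPSYN-F1")
  g3 <- compressToComplexes(createGroup(kb, "g3", "g3", "Gene"), kb)
  expect_identical(memberIds(g3), "PP-G3")
  empty <- compressToComplexes(createGroup(kb, "e", character(0), "Gene"), kb)
  expect_length(empty, 0)
  # never more members than input genes (random subsets of a generated KB)
  kb2 <- genKb()
  genes <- frameIds(kb2, "Gene")
  set.seed(3)
  for (i in 1:20) {
    g <- createGroup(kb2, "G", sample(genes, sample(2:30, 1)), "Gene")
    expect_lte(length(compressToComplexes(g, kb2)), length(g))
  }
})

test_that("genes with no product are reported, not silently dropped", {
  kb <- makeTestKb(list(fr("orphan", "Gene"), fr("g", "Gene", product = "pp"),
                        fr("pp", "Polypeptide")))
  g <- compressToComplexes(createGroup(kb, "G", c("orphan", "g"), "Gene"), kb)
  expect_identical(memberIds(g), "pp")
  expect_identical(groupMetadata(g)$report$noProduct, "orphan")
})

test_that("pathway closure holds on generated knowledge bases", {
  kb <- genKb()
  genes <- frameIds(kb, "Gene")
  inPwy <- genes[vapply(genes, function(g)
    length(kgroups:::.genePathways(kb, g)) > 0, logical(1))]
  set.seed(5)
  for (i in 1:10) {
    sel <- sample(genes, 25)
    g <- createGroup(kb, "G", sel, "Gene")
    g <- addTransformColumn(g, kb, "pathways")
    pg <- columnToGroup(g, kb, 2)
    pg <- addTransformColumn(pg, kb, "genes")
    back <- unique(unlist(columnCells(pg, 2)))
    expect_true(all(intersect(sel, inPwy) %in% back))
  }
})

test_that("transforms are pure and return frames of the declared class", {
  kb <- genKb()
  g <- createGroup(kb, "G", frameIds(kb, "Gene")[1:15], "Gene")
  a <- addTransformColumn(g, kb, "regulators")
  b <- addTransformColumn(g, kb, "regulators")
  expect_identical(columnCells(a, 2), columnCells(b, 2))
  classOf <- function(cells) unique(vapply(unlist(cells), function(v)
    frameClass(kb, v), character(1)))
  expect_true(all(classOf(columnCells(a, 2)) %in%
                    c("Polypeptide", "ProteinComplex")))
  p <- addTransformColumn(g, kb, "pathways")
  expect_identical(classOf(columnCells(p, 2)), "Pathway")
  o <- addTransformColumn(g, kb, "operons")
  expect_identical(classOf(columnCells(o, 2)), "Operon")
})

test_that("promoter flank extraction is strand-aware and clamped", {
  kb <- miniKb()
  g <- createGroup(kb, "g1", "g1", "Gene")
  pf <- promoterFlanks(g, kb, 50, 50)
  s <- columnCells(pf, 2)[[1]]
  expect_identical(nchar(s), 101L)
  expect_identical(s, subsequence(kb, seqRegion("CHR1", 1510, 1610, "+")))
  pf0 <- promoterFlanks(g, kb, 0, 0)
  expect_identical(nchar(columnCells(pf0, 2)[[1]]), 1L)
  # a gene with no operon/promoter yields an empty cell
  kb2 <- makeTestKb(list(fr("lone", "Gene")))
  g2 <- promoterFlanks(createGroup(kb2, "l", "lone", "Gene"), kb2)
  expect_identical(columnCells(g2, 2)[[1]], character(0))
  # minus-strand promoter: upstream lies to the right
  kb3 <- genKb()
  minusOps <- Filter(function(p)
    identical(slotValues(kb3, p, "strand"), "-"), frameIds(kb3, "Promoter"))
  pm <- minusOps[1]
  gene <- slotValues(kb3, slotValues(kb3, pm, "controls"), "operon-genes")[1]
  gg <- promoterFlanks(createGroup(kb3, "m", gene, "Gene"), kb3, 30, 10)
  pos <- kgroups:::.slotNum(kb3, pm, "pos")
  expect_identical(columnCells(gg, 2)[[1]],
                   subsequence(kb3, seqRegion("CHR1", pos - 10, pos + 30, "-")))
})
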