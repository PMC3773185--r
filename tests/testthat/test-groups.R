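# groups_core: creation, columns, column-to-group, set/filter algebra,
# import/export, persistence, special groups.

test_that("group creation dedups members and enforces one class", {
  kb <- miniKb()
  g <- createGroup(kb, "G", c("atpA", "atpB", "atpA"), "Gene")
  expect_length(g, 2)
  expect_identical(memberIds(g), c("atpA", "atpB"))
  e <- createGroup(kb, "E", character(0), "Gene")
  expect_length(e, 0)
  expect_error(createGroup(kb, "Bad", c("atpA", "PWY-1"), "Gene"),
               class = "kgTypeError")
})

test_that("property columns hold raw slot values and reject unknown slots", {
  kb <- miniKb()
  g <- createGroup(kb, "G", c("atpA", "atpB"), "Gene")
  g <- addPropertyColumn(g, kb, "product")
  expect_identical(columnCells(g, 2), list("PP-ATPA", "PP-ATPB"))
  g <- addPropertyColumn(g, kb, "annotated-to")
  expect_identical(columnCells(g, 3)[[1]], c("GO-CC-1", "GO-MF-1"))
  cg <- createGroup(kb, "C", "cpd-A", "Compound")
  err <- tryCatch(addPropertyColumn(cg, kb, "product"), kgSchemaError = identity)
  expect_s3_class(err, "kgSchemaError")
  expect_match(conditionMessage(err), "valid slots")
})

test_that("column-to-group takes the non-redundant union with a reverse map", {
  kb <- miniKb()
  g <- createGroup(kb, "g12", c("g1", "g2"), "Gene")
  g <- addTransformColumn(g, kb, "regulators")
  r <- columnToGroup(g, kb, 2)
  expect_identical(memberIds(r), "CRPX")
  expect_identical(columnCells(r, 2), list(c("g1", "g2")))
  # dedup bound on a generated KB
  kb2 <- genKb()
  gg <- createGroup(kb2, "some", frameIds(kb2, "Gene")[1:20], "Gene")
  gg <- addTransformColumn(gg, kb2, "pathways")
  rr <- columnToGroup(gg, kb2, 2)
  expect_lte(length(rr), sum(lengths(columnCells(gg, 2))))
  # empty column -> empty group; literal column -> type error
  eg <- createGroup(kb, "atpA", "atpA", "Gene")
  eg <- addTransformColumn(eg, kb, "pathways")
  expect_length(columnToGroup(eg, kb, 2), 0)
  ng <- addPropertyColumn(createGroup(kb, "n", "g1", "Gene"), kb, "start")
  expect_error(columnToGroup(ng, kb, 2), class = "kgTypeError")
})

test_that("set algebra obeys the usual laws on random same-class groups", {
  kb <- genKb()
  genes <- frameIds(kb, "Gene")
  set.seed(7)
  for (i in 1:50) {
    a <- createGroup(kb, "A", sample(genes, sample(5:40, 1)), "Gene")
    b <- createGroup(kb, "B", sample(genes, sample(5:40, 1)), "Gene")
    u <- groupUnion(a, b); n <- groupIntersection(a, b)
    expect_equal(length(u) + length(n), length(a) + length(b))
    expect_length(groupDifference(a, a), 0)
    expect_identical(memberIds(groupUnion(a, a)), memberIds(a))
    expect_setequal(memberIds(u), memberIds(groupUnion(b, a)))
    expect_identical(memberIds(groupUnion(a, createGroup(kb, "E",
                       character(0), "Gene"))), memberIds(a))
    expect_setequal(memberIds(groupDifference(a, b)),
                    setdiff(memberIds(a), memberIds(b)))
  }
  pw <- createGroup(kb, "P", frameIds(kb, "Pathway")[1], "Pathway")
  g1 <- createGroup(kb, "G", genes[1], "Gene")
  expect_error(groupUnion(g1, pw), class = "kgTypeError")
})

test_that("name filter matches names and synonyms case-insensitively", {
  kb <- miniKb()
  all <- copyEditable(specialGroup(kb, "Gene"))
  expect_identical(memberIds(filterByName(all, kb, "atp")),
                   sort(sprintf("atp%s", LETTERS[1:8])))
  expect_length(filterByName(all, kb, ""), length(all))
  expect_length(filterByName(all, kb, "zzz"), 0)
  expect_identical(memberIds(filterByName(all, kb, "UNCA")), "atpA")
})

test_that("threshold filter keeps rows where any cell value passes", {
  kb <- miniKb()
  p <- writeTsv(c("id\tval", "atpA\t1.5", "atpB\t2.5", "atpC\t"))
  g <- importGroupTsv(kb, p, "Gene", header = "yes")
  expect_length(g, 3)
  kept <- filterByThreshold(g, 2, ">", 2)
  expect_identical(memberIds(kept), "atpB")
  expect_length(filterByThreshold(g, 2, ">", -1e9), 2)  # empty cell never passes
  expect_length(filterByThreshold(g, 2, "<=", 2.5), 2)
  expect_length(filterByThreshold(g, 2, "=", 1.5), 1)
  sp <- writeTsv(c("id\tval", "atpA\thello"))
  sg <- importGroupTsv(kb, sp, "Gene", header = "yes")
  expect_error(filterByThreshold(sg, 2, ">", 1), class = "kgTypeError")
})

test_that("TSV import resolves tokens and reports problems", {
  kb <- miniKb()
  p <- writeTsv(c("atpA\t1.2", "atpB\t3.4"))
  g <- importGroupTsv(kb, p, "Gene")
  expect_length(g, 2)
  expect_identical(groupColumn(g, 2)@valueType, "number")
  expect_identical(unlist(columnCells(g, 2)), c(1.2, 3.4))

  p2 <- writeTsv(c("atpA\t1", "no-such-gene\t2", "uncA\t3"))
  g2 <- importGroupTsv(kb, p2, "Gene")
  rep <- groupMetadata(g2)$importReport
  expect_identical(rep$unresolved, "no-such-gene")
  expect_identical(rep$duplicates, "uncA")   # synonym of atpA, already present
  expect_length(g2, 1)

  # header auto-detection: unresolvable first token + >= 2 columns
  p3 <- writeTsv(c("gene\texpr", "atpA\t2.5"))
  g3 <- importGroupTsv(kb, p3, "Gene")
  expect_length(g3, 1)
  expect_identical(columnHeaders(g3), c("Gene", "expr"))

  expect_warning(importGroupTsv(kb, writeTsv("nope\t1"), "Gene"),
                 "resolved")
})

test_that("export writes deterministic TSV with ' // ' multi-value joins", {
  kb <- miniKb()
  g <- createGroup(kb, "g12", c("g1", "g2"), "Gene")
  g <- addTransformColumn(g, kb, "regulators")
  r <- columnToGroup(g, kb, 2)
  out <- tempfile(fileext = ".tsv")
  exportGroupTsv(r, kb, out)
  lines <- readLines(out)
  expect_length(lines, 2)                       # header + 1 row
  expect_match(lines[2], "g1 // g2", fixed = TRUE)
  out2 <- tempfile(); exportGroupTsv(r, kb, out2)
  expect_identical(readLines(out), readLines(out2))
})

test_that("import -> export -> import is a fixed point", {
  kb <- miniKb()
  p <- writeTsv(c("gene\texpr\tnote", "atpA\t1.5\thi", "g1\t-2\t",
                  "atpB\t0.25\tlow"))
  g1 <- importGroupTsv(kb, p, "Gene", header = "yes")
  out <- tempfile(); exportGroupTsv(g1, kb, out)
  g2 <- importGroupTsv(kb, out, "Gene", header = "yes")
  expect_identical(memberIds(g2), memberIds(g1))
  expect_identical(lapply(2:3, function(i) columnCells(g2, i)),
                   lapply(2:3, function(i) columnCells(g1, i)))
  out2 <- tempfile(); exportGroupTsv(g2, kb, out2)
  expect_identical(readLines(out), readLines(out2))
})

test_that("group persistence round-trips all columns with provenance", {
  kb <- miniKb()
  g <- createGroup(kb, "g12", c("g1", "g2"), "Gene",
                   description = "two regulated genes")
  g <- addPropertyColumn(g, kb, "product")
  g <- addTransformColumn(g, kb, "coding-region")
  g <- addTransformColumn(g, kb, "regulators")
  path <- tempfile(fileext = ".grp")
  saveGroup(g, path)
  g2 <- loadGroup(path)
  expect_identical(memberIds(g2), memberIds(g))
  expect_identical(g2@description, g@description)
  expect_identical(columnHeaders(g2), columnHeaders(g))
  expect_identical(columnCells(g2, 2), columnCells(g, 2))
  expect_identical(lapply(columnCells(g2, 3)[[1]], kgroups:::.regionKey),
                   lapply(columnCells(g, 3)[[1]], kgroups:::.regionKey))
  # provenance survives: recomputing the transform column reproduces it
  g3 <- recomputeColumn(g2, kb, 4)
  expect_identical(columnCells(g3, 4), columnCells(g, 4))
})

test_that("persistence rejects other versions and truncated files", {
  kb <- miniKb()
  g <- createGroup(kb, "g", "g1", "Gene")
  path <- tempfile(); saveGroup(g, path)
  txt <- readLines(path, warn = FALSE)
  bad <- tempfile()
  writeLines(sub("\"version\":1", "\"version\":2", txt), bad)
  expect_error(loadGroup(bad), class = "kgVersionError")
  trunc <- tempfile()
  writeLines(substr(paste(txt, collapse = ""), 1, 40), trunc)
  expect_error(loadGroup(trunc), class = "kgParseError")
})

test_that("special groups mirror the KB and reject mutation", {
  kb <- miniKb()
  sg <- specialGroup(kb, "Gene")
  expect_length(sg, 11)
  expect_true(sg@readOnly)
  expect_error(addMembers(sg, "g1", kb), class = "kgReadOnlyError")
  expect_error(addPropertyColumn(sg, kb, "product"),
               class = "kgReadOnlyError")
  ed <- copyEditable(sg)
  expect_false(ed@readOnly)
  before <- length(sg)
  ed2 <- addMembers(ed, character(0), kb)
  expect_length(ed2, before)
  expect_length(sg, before)   # original untouched
})

test_that("derived columns can be deleted and recomputed identically", {
  kb <- genKb()
  g <- createGroup(kb, "G", frameIds(kb, "Gene")[1:10], "Gene")
  g <- addPropertyColumn(g, kb, "product")
  g <- addTransformColumn(g, kb, "pathways")
  for (i in c(2L, 3L)) {
    orig <- columnCells(g, i)
    g2 <- recomputeColumn(g, kb, i)
    expect_identical(columnCells(g2, i), orig)
  }
  g3 <- deleteColumn(g, 2)
  expect_identical(columnHeaders(g3), c("Gene", "pathways"))
})
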