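# Shared fixtures and independent oracles for the test suite.

# memoised fixtures (loading/generating once per test run)
.fixtureCache <- new.env(parent = emptyenv())

miniKb <- function() {
  if (is.null(.fixtureCache$mini))
    .fixtureCache$mini <- loadKb(minitoyPath())
  .fixtureCache$mini
}

genKb <- function() {
  if (is.null(.fixtureCache$gen))
    .fixtureCache$gen <- generateToyPgdb(1)
  .fixtureCache$gen
}

# build a KB from forward-slot frame stubs (inverses filled automatically)
makeTestKb <- function(frames, sequences = NULL) {
  kb <- kgroups:::.newKb(kgroups:::.withInverses(frames), sequences)
  validateKb(kb)
  kb
}

fr <- kgroups:::.fr

# small GO testbed: 12 genes, one ontology with root R, parents P1/P2 and a
# two-parent leaf term T; direct annotations chosen so true-path
# propagation matters.
#   direct: T = g01..g04, P1 += g05,g06, P2 += g06,g07,g08, root += g09
pcToyKb <- function() {
  if (!is.null(.fixtureCache$pctoy)) return(.fixtureCache$pctoy)
  g <- sprintf("g%02d", 1:12)
  frames <- c(
    lapply(g, function(x) fr(x, "Gene")),
    list(
      fr("R", "GOTerm", ontology = "molecular-function", annotates = "g09"),
      fr("P1", "GOTerm", ontology = "molecular-function", is_a = "R",
         annotates = c("g05", "g06")),
      fr("P2", "GOTerm", ontology = "molecular-function", is_a = "R",
         annotates = c("g06", "g07", "g08")),
      fr("T", "GOTerm", ontology = "molecular-function",
         is_a = c("P1", "P2"), annotates = c("g01", "g02", "g03", "g04")),
      # a single-parent sibling term for the reduction checks
      fr("S", "GOTerm", ontology = "molecular-function", is_a = "P1",
         annotates = c("g05"))
    ))
  .fixtureCache$pctoy <- makeTestKb(frames)
  .fixtureCache$pctoy
}

# independent hypergeometric upper-tail oracle: exhaustive enumeration of
# all C(N, n) draws of n from N with the first K elements as successes
enumTail <- function(k, n, K, N) {
  if (k == 0) return(1)
  if (n == 0) return(0)
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)
  sum(hits >= k) / ncol(draws)
}

writeTsv <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}
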