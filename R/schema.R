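# Knowledge-base schema: the frame classes and the directional relation slots
# (each with a declared inverse) that every loaded or generated KB must obey.

#' Frame classes recognised by the knowledge-base schema
#'
#' @return Character vector of class names.
#' @export
kbClasses <- function() {
  c("Gene", "Polypeptide", "ProteinComplex", "Reaction", "Pathway",
    "PathwayClass", "Compound", "Promoter", "Operon", "BindingSite",
    "GOTerm", "Replicon", "Organism")
}

# classes that can act as proteins (enzymes, regulators, ligand targets)
.PROTEIN <- c("Polypeptide", "ProteinComplex")

# slot table: domains/range are "|"-separated class lists; kind is "ref",
# "number" or "string"; inverse is NA for literal slots.
.SLOT_TABLE <- local({
  P <- paste(.PROTEIN, collapse = "|")
  LOC <- "Gene|Promoter|BindingSite"  # located features
  m <- rbind(
    c("product",                "Gene",         "ref",    "Polypeptide",  "gene"),
    c("gene",                   "Polypeptide",  "ref",    "Gene",         "product"),
    c("component-of",           "Polypeptide",  "ref",    "ProteinComplex", "components"),
    c("components",             "ProteinComplex","ref",   "Polypeptide",  "component-of"),
    c("catalyzes",              P,              "ref",    "Reaction",     "enzymes"),
    c("enzymes",                "Reaction",     "ref",    P,              "catalyzes"),
    c("in-pathway",             "Reaction",     "ref",    "Pathway",      "reactions"),
    c("reactions",              "Pathway",      "ref",    "Reaction",     "in-pathway"),
    c("left",                   "Reaction",     "ref",    "Compound",     "left-of"),
    c("right",                  "Reaction",     "ref",    "Compound",     "right-of"),
    c("left-of",                "Compound",     "ref",    "Reaction",     "left"),
    c("right-of",               "Compound",     "ref",    "Reaction",     "right"),
    c("direction",              "Reaction",     "string", NA,             NA),
    c("in-class",               "Pathway",      "ref",    "PathwayClass", "class-pathways"),
    c("class-pathways",         "PathwayClass", "ref",    "Pathway",      "in-class"),
    c("parent-class",           "PathwayClass", "ref",    "PathwayClass", "sub-classes"),
    c("sub-classes",            "PathwayClass", "ref",    "PathwayClass", "parent-class"),
    c("regulates",              P,              "ref",    "Gene",         "regulated-by"),
    c("regulated-by",           "Gene",         "ref",    P,              "regulates"),
    c("sigma-factor",           P,              "string", NA,             NA),
    c("binds-sites",            P,              "ref",    "BindingSite",  "bound-by"),
    c("bound-by",               "BindingSite",  "ref",    P,              "binds-sites"),
    c("regulates-promoter",     "BindingSite",  "ref",    "Promoter",     "binding-sites"),
    c("binding-sites",          "Promoter",     "ref",    "BindingSite",  "regulates-promoter"),
    c("controls",               "Promoter",     "ref",    "Operon",       "promoter"),
    c("promoter",               "Operon",       "ref",    "Promoter",     "controls"),
    c("operon-genes",           "Operon",       "ref",    "Gene",         "in-operon"),
    c("in-operon",              "Gene",         "ref",    "Operon",       "operon-genes"),
    c("annotated-to",           "Gene",         "ref",    "GOTerm",       "annotates"),
    c("annotates",              "GOTerm",       "ref",    "Gene",         "annotated-to"),
    c("is-a",                   "GOTerm",       "ref",    "GOTerm",       "children"),
    c("children",               "GOTerm",       "ref",    "GOTerm",       "is-a"),
    c("ontology",               "GOTerm",       "string", NA,             NA),
    c("activates",              "Compound",     "ref",    P,              "activated-by"),
    c("activated-by",           P,              "ref",    "Compound",     "activates"),
    c("inhibits",               "Compound",     "ref",    P,              "inhibited-by"),
    c("inhibited-by",           P,              "ref",    "Compound",     "inhibits"),
    c("ligand-of",              "Compound",     "ref",    P,              "ligands"),
    c("ligands",                P,              "ref",    "Compound",     "ligand-of"),
    c("tf-ligand-regulates",    "Compound",     "ref",    "Gene",         "tf-ligand-regulated-by"),
    c("tf-ligand-regulated-by", "Gene",         "ref",    "Compound",     "tf-ligand-regulates"),
    c("replicon",               LOC,            "ref",    "Replicon",     "features"),
    c("features",               "Replicon",     "ref",    LOC,            "replicon"),
    c("start",                  "Gene|BindingSite", "number", NA,         NA),
    c("end",                    "Gene|BindingSite", "number", NA,         NA),
    c("strand",                 LOC,            "string", NA,             NA),
    c("pos",                    "Promoter",     "number", NA,             NA),
    c("genome",                 "Organism",     "ref",    "Replicon",     "organism"),
    c("organism",               "Replicon",     "ref",    "Organism",     "genome")
  )
  d <- data.frame(slot = m[, 1], domains = m[, 2], kind = m[, 3],
                  range = m[, 4], inverse = m[, 5], stringsAsFactors = FALSE)
  rownames(d) <- d$slot
  d
})

.GO_ONTOLOGIES <- c("molecular-function", "biological-process", "cellular-location")

.slotDef <- function(slot) {
  if (!slot %in% rownames(.SLOT_TABLE)) return(NULL)
  .SLOT_TABLE[slot, ]
}

.splitClasses <- function(x) strsplit(x, "|", fixed = TRUE)[[1]]

#' Slots defined for a frame class
#'
#' Lists the relation and literal slots that the KB schema allows on frames of
#' a given class, e.g. the slots offered by the "add property column" menu.
#'
#' @param class A frame class name (see [kbClasses()]).
#' @return Character vector of slot names.
#' @export
slotsForClass <- function(class) {
  stopifnot(is.character(class), length(class) == 1)
  hit <- vapply(.SLOT_TABLE$domains,
                function(d) class %in% .splitClasses(d), logical(1))
  .SLOT_TABLE$slot[hit]
}

# ---- classed error conditions -------------------------------------------

kgStop <- function(class, msg, ...) {
  stop(structure(class = c(class, "kgError", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

kgParseError      <- function(msg, ...) kgStop("kgParseError", msg, ...)
kgIntegrityError  <- function(msg, ...) kgStop("kgIntegrityError", msg, ...)
kgTypeError       <- function(msg, ...) kgStop("kgTypeError", msg, ...)
kgSchemaError     <- function(msg, ...) kgStop("kgSchemaError", msg, ...)
kgReadOnlyError   <- function(msg, ...) kgStop("kgReadOnlyError", msg, ...)
kgArgumentError   <- function(msg, ...) kgStop("kgArgumentError", msg, ...)
kgBoundsError     <- function(msg, ...) kgStop("kgBoundsError", msg, ...)
kgApplicabilityError <- function(msg, ...) kgStop("kgApplicabilityError", msg, ...)
kgVersionError    <- function(msg, ...) kgStop("kgVersionError", msg, ...)
kgConfigError     <- function(msg, ...) kgStop("kgConfigError", msg, ...)
kgDegenerateRegionError <- function(msg, ...) kgStop("kgDegenerateRegionError", msg, ...)
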