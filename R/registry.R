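#' Morph taxonomy registry
#'
#' The female wing patterns of *Papilio dardanus* are a controlled vocabulary:
#' each named form (morph) belongs to one of nine morph groups of similar
#' looking forms, each recognised subspecies carries a documented list of
#' morphs, and a small fixed set of forms count as "imperfect" mimics (forms
#' mixing elements of several patterns, plus specimens recorded simply as
#' `intermediate`). A `morph_registry` bundles these lookup tables.
#'
#' @name morph_registry
NULL

#' Normalise a morph or subspecies label
#'
#' Lower-cases, strips a leading "f." (forma) prefix, removes asterisks and
#' underscores used for typographic emphasis, and collapses whitespace.
#' Internal hyphens (as in `proto-cenea`) are preserved.
#'
#' @param x character vector of labels.
#' @return normalised character vector.
#' @export
normalise_morph <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x <- gsub("[*_\"']", "", x)
  x <- sub("^f[. ]+", "", x)
  x <- gsub("\\s+", " ", trimws(x))
  x
}

#' Construct a morph registry
#'
#' @param morph_to_group named character vector: morph -> morph group.
#' @param subspecies_to_morphs named list: subspecies -> character vector of
#'   morphs (order preserved).
#' @param subspecies_to_clade named character vector: subspecies -> one of
#'   `Western`, `Eastern`, `IndianOcean`, `unassigned`.
#' @param imperfect_morphs character vector of morph names counted as
#'   imperfect mimics.
#' @return a `morph_registry`.
#' @export
morph_registry <- function(morph_to_group, subspecies_to_morphs,
                           subspecies_to_clade, imperfect_morphs) {
  names(morph_to_group) <- normalise_morph(names(morph_to_group))
  subspecies_to_morphs <- lapply(subspecies_to_morphs, normalise_morph)
  names(subspecies_to_morphs) <- normalise_morph(names(subspecies_to_morphs))
  names(subspecies_to_clade) <- normalise_morph(names(subspecies_to_clade))
  imperfect_morphs <- normalise_morph(imperfect_morphs)

  clades <- c("Western", "Eastern", "IndianOcean", "unassigned")
  if (!all(subspecies_to_clade %in% clades)) {
    stop("clades must be one of: ", paste(clades, collapse = ", "))
  }
  listed <- unique(unlist(subspecies_to_morphs, use.names = FALSE))
  orphan <- setdiff(listed, names(morph_to_group))
  if (length(orphan) > 0) {
    stop("morph(s) without a group assignment: ",
         paste(orphan, collapse = ", "))
  }
  structure(
    list(morph_to_group = morph_to_group,
         subspecies_to_morphs = subspecies_to_morphs,
         subspecies_to_clade = subspecies_to_clade,
         imperfect_morphs = imperfect_morphs),
    class = "morph_registry"
  )
}

#' @export
print.morph_registry <- function(x, ...) {
  cat("Morph registry:\n")
  cat("  morphs:", length(x$morph_to_group),
      "in", length(unique(x$morph_to_group)), "groups\n")
  cat("  subspecies:", length(x$subspecies_to_morphs), "\n")
  cat("  imperfect forms:", paste(x$imperfect_morphs, collapse = ", "), "\n")
  invisible(x)
}

#' Default registry for the P. dardanus system
#'
#' Encodes the published subspecies-to-morph table (eleven recognised
#' subspecies; disputed names are omitted), the clade membership of each
#' subspecies (Western/Eastern mainland lineages and the Indian Ocean
#' islands), the nine morph groups (with f. leighi placed in the planemoides
#' group, the hippocoon group containing hippocoon, hippocoonides and
#' meseres, and the Ethiopian tailed variants assigned to their untailed base
#' form's group), and the fixed set of imperfect-mimic forms: trimeni,
#' dorrippoides, dionysoides, proto-cenea, mixtoides, swynnertoni, carpenteri
#' and lamborni, together with the label `intermediate` used for specimens
#' combining attributes of more than one group.
#'
#' @return a [morph_registry].
#' @export
default_morph_registry <- function() {
  morph_to_group <- c(
    # male-like forms of the non-mimetic subspecies
    antinorii   = "male-like",
    flavicornis = "male-like",
    atavica     = "male-like",
    ochracea    = "male-like",
    meriones    = "male-like",
    humbloti    = "male-like",
    # hippocoon group: hippocoon, hippocoonides and the intermediate meseres
    hippocoon      = "hippocoon",
    hippocoonides  = "hippocoon",
    meseres        = "hippocoon",
    niavoides      = "hippocoon",   # tailed variant of hippocoonides
    trimeni        = "hippocoon",
    mixtoides      = "hippocoon",
    cenea          = "cenea",
    salaami        = "cenea",
    "proto-cenea"  = "cenea",
    vaccaroi       = "cenea",       # tailed variant of cenea
    trophonius     = "trophonius",
    ruspinae       = "trophonius",  # tailed variant of trophonius
    dorrippoides   = "trophonius",
    planemoides    = "planemoides",
    leighi         = "planemoides",
    niobe          = "niobe",
    niobioides     = "niobe",
    lamborni       = "niobe",
    natalica       = "natalica",
    poultoni       = "poultoni",
    weinholti      = "poultoni",    # tailed variant of poultoni
    swynnertoni    = "poultoni",
    carpenteri     = "poultoni",
    dionysos       = "dionysos",
    dionysoides    = "dionysos",
    # bucket for specimens mixing attributes of more than one group
    intermediate   = "intermediate"
  )
  subspecies_to_morphs <- list(
    dardanus = c("hippocoon", "dionysos", "planemoides", "trophonius",
                 "cenea", "niobe", "lamborni", "niobioides", "natalica",
                 "mixtoides"),
    tibullus = c("cenea", "trophonius", "hippocoonides", "salaami",
                 "natalica", "trimeni", "poultoni", "lamborni", "mixtoides"),
    cenea = c("cenea", "leighi", "trophonius", "hippocoonides", "salaami",
              "natalica"),
    ochraceana = "ochracea",
    flavicornis = c("flavicornis", "atavica"),
    antinorii = c("antinorii", "niavoides", "ruspinae", "weinholti",
                  "vaccaroi"),
    meriones = "meriones",
    humbloti = "humbloti",
    meseres = c("hippocoonides", "cenea", "meseres", "lamborni",
                "planemoides", "salaami", "trimeni", "mixtoides"),
    polytrophus = c("hippocoonides", "cenea", "meseres", "poultoni",
                    "lamborni", "planemoides", "trimeni", "swynnertoni",
                    "carpenteri", "mixtoides"),
    byatti = character(0)
  )
  subspecies_to_clade <- c(
    dardanus = "Western", tibullus = "Eastern", cenea = "Eastern",
    ochraceana = "Western", flavicornis = "Eastern", antinorii = "Eastern",
    meriones = "IndianOcean", humbloti = "IndianOcean", meseres = "Eastern",
    polytrophus = "Eastern", byatti = "Eastern"
  )
  imperfect <- c("trimeni", "dorrippoides", "dionysoides", "proto-cenea",
                 "mixtoides", "swynnertoni", "carpenteri", "lamborni",
                 "intermediate")
  morph_registry(morph_to_group, subspecies_to_morphs, subspecies_to_clade,
                 imperfect)
}

#' Is a morph an imperfect mimic?
#'
#' Normalises the label (see [normalise_morph]) and tests membership in the
#' registry's imperfect set. Unknown morphs are `FALSE`.
#'
#' @param morph character vector of morph labels (may carry an "f." prefix).
#' @param reg a [morph_registry]; defaults to [default_morph_registry()].
#' @return logical vector.
#' @export
is_imperfect <- function(morph, reg = default_morph_registry()) {
  normalise_morph(morph) %in% reg$imperfect_morphs
}

#' Morph group of a morph
#'
#' @param morph character vector of morph labels.
#' @param reg a [morph_registry].
#' @return character vector of group names; `NA` for unknown morphs.
#' @export
morph_group_of <- function(morph, reg = default_morph_registry()) {
  unname(reg$morph_to_group[normalise_morph(morph)])
}

#' Morph list of a subspecies
#'
#' Returns the registry's documented morph list for a subspecies, in its
#' published order (possibly empty, e.g. for ssp. byatti whose females are
#' unrecorded in the source table).
#'
#' @param ssp subspecies name (single string).
#' @param reg a [morph_registry].
#' @return character vector of morph names.
#' @export
morphs_for_subspecies <- function(ssp, reg = default_morph_registry()) {
  key <- normalise_morph(ssp)
  if (!key %in% names(reg$subspecies_to_morphs)) {
    stop("unknown subspecies '", ssp, "'; valid keys: ",
         paste(sort(names(reg$subspecies_to_morphs)), collapse = ", "))
  }
  reg$subspecies_to_morphs[[key]]
}
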