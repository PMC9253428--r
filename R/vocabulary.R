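#' Controlled drug vocabulary
#'
#' A drug vocabulary names the index drug, the set of anti-allergic marker
#' drugs used as the surrogate signal of an allergic reaction, and the ordered
#' list of target concomitant medications whose co-prescription risk is
#' estimated. All names are normalized (trimmed, internal whitespace squeezed,
#' case-folded) so matching against claims rows is exact.
#'
#' @param xyp_name Name of the index drug (default `"xiyanping"`).
#' @param marker_drugs Character vector of marker-drug names. The default is
#'   the four-drug anti-allergic panel: an antihistamine (promethazine), a
#'   corticosteroid (dexamethasone), calcium gluconate and adrenaline.
#' @param target_concomitants Ordered character vector of target concomitant
#'   medications; order is preserved in all reports. The default is the
#'   standard 25-drug panel of the most frequently co-prescribed medications.
#' @return An object of class `drug_vocabulary`: a list with elements
#'   `xyp_name`, `marker_drugs`, `target_concomitants` (all normalized).
#' @examples
#' v <- drug_vocabulary()
#' length(v$target_concomitants)  # 25
#' @export
drug_vocabulary <- function(xyp_name = "xiyanping",
                            marker_drugs = c("promethazine", "dexamethasone",
                                             "calcium gluconate", "adrenaline"),
                            target_concomitants = default_concomitants()) {
  xyp_name <- normalize_drug(xyp_name)
  marker_drugs <- normalize_drug(marker_drugs)
  target_concomitants <- normalize_drug(target_concomitants)
  if (any(!nzchar(c(xyp_name, marker_drugs, target_concomitants))))
    stop("drug names must be non-empty after normalization")
  groups <- list(xyp = xyp_name, markers = marker_drugs,
                 concomitants = target_concomitants)
  all_names <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(all_names))
    stop("index drug, marker drugs and target concomitants must be pairwise disjoint")
  structure(list(xyp_name = xyp_name,
                 marker_drugs = marker_drugs,
                 target_concomitants = target_concomitants),
            class = "drug_vocabulary")
}

#' Default 25-drug target concomitant panel
#'
#' The standard panel, in reporting order: antibiotics, vitamins,
#' bronchodilators, mucolytics and supportive infusions most frequently
#' co-prescribed with the index injection.
#'
#' @return Character vector of 25 normalized drug names.
#' @export
default_concomitants <- function() {
  c("amoxicillin-clavulanate", "penicillin", "cefuroxime", "cefathiamidine",
    "cefoperazone-sulbactam", "ceftriaxone", "ceftazidime", "cefazolin",
    "meropenem", "amikacin", "gentamicin", "azithromycin", "levofloxacin",
    "moxifloxacin", "vitamin b6", "vitamin c", "aminophylline", "ambroxol",
    "heparin", "ribavirin", "lidocaine", "pantoprazole", "sodium bicarbonate",
    "bromhexine", "potassium chloride")
}

#' Normalize a drug name
#'
#' Trims leading/trailing whitespace, squeezes internal runs of whitespace to
#' a single space, and lower-cases.
#'
#' @param x Character vector.
#' @return Normalized character vector.
#' @export
normalize_drug <- function(x) {
  tolower(gsub("\\s+", " ", trimws(as.character(x))))
}

# Column-safe identifier for a drug name (used for exposure-matrix columns).
drug_key <- function(x) gsub("[^a-z0-9]+", "_", normalize_drug(x))
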