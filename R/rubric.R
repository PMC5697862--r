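#' Pathogenicity evidence for one variant
#'
#' The point-based rubric used in the mitochondrial field scores a variant on
#' reported and experimental evidence; the decisive ("gold standard")
#' criteria are single muscle fibre analysis and trans-mitochondrial cybrid
#' (or equivalent in-vitro) studies that tie the genotype to a biochemical
#' phenotype.
#'
#' @param independent_reports Number of independent disease reports.
#' @param evolutionary_conservation,heteroplasmy,segregation_with_phenotype,biochemical_defect,single_fibre_evidence,cybrid_or_in_vitro_evidence
#'   Logical evidence flags.
#' @return List of class `mt_evidence`.
#' @export
pathogenicity_evidence <- function(independent_reports = 0,
                                   evolutionary_conservation = FALSE,
                                   heteroplasmy = FALSE,
                                   segregation_with_phenotype = FALSE,
                                   biochemical_defect = FALSE,
                                   single_fibre_evidence = FALSE,
                                   cybrid_or_in_vitro_evidence = FALSE) {
  if (independent_reports < 0) stop("independent_reports must be >= 0")
  structure(list(
    independent_reports = independent_reports,
    evolutionary_conservation = isTRUE(evolutionary_conservation),
    heteroplasmy = isTRUE(heteroplasmy),
    segregation_with_phenotype = isTRUE(segregation_with_phenotype),
    biochemical_defect = isTRUE(biochemical_defect),
    single_fibre_evidence = isTRUE(single_fibre_evidence),
    cybrid_or_in_vitro_evidence = isTRUE(cybrid_or_in_vitro_evidence)
  ), class = "mt_evidence")
}

#' Load a scoring rubric from YAML
#'
#' The classification code is value-agnostic: all point weights and class
#' bands live in the config. The packaged default
#' (`inst/extdata/yarham_rubric.yaml`) carries weights transcribed from the
#' published point-based scheme, class bands (score thresholds for
#' neutral/possibly/probably) and a functional gate: "definitely" requires
#' single-fibre or cybrid evidence, otherwise the call is demoted to
#' "probably".
#'
#' @param path YAML file; default is the packaged rubric.
#' @return List of class `mt_rubric` with `weights`, `multi_report_threshold`,
#'   `class_bands` and `functional_gate`.
#' @export
load_rubric <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "yarham_rubric.yaml",
                        package = "mttrnascreen", mustWork = TRUE)
  }
  cfg <- yaml::read_yaml(path)
  rubric(weights = unlist(cfg$weights),
         multi_report_threshold = cfg$multi_report_threshold %||% 2,
         class_bands = unlist(cfg$class_bands),
         functional_gate = isTRUE(cfg$functional_gate))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a scoring rubric
#'
#' @param weights Named numeric vector of points per satisfied criterion;
#'   names must match the [pathogenicity_evidence()] fields (with
#'   `independent_reports` scored when the count reaches
#'   `multi_report_threshold`).
#' @param multi_report_threshold Minimum report count that earns the
#'   `independent_reports` points.
#' @param class_bands Named numeric vector `c(possibly=, probably=)`: the
#'   minimum total score for each class; scores below `possibly` are neutral.
#'   Must be strictly increasing.
#' @param functional_gate If `TRUE`, scores in the top band are called
#'   "definitely" only when single-fibre or cybrid evidence is present, and
#'   "probably" otherwise.
#' @return List of class `mt_rubric`.
#' @export
rubric <- function(weights, multi_report_threshold = 2, class_bands,
                   functional_gate = TRUE) {
  if (any(weights < 0)) stop("rubric weights must be >= 0")
  if (!all(c("possibly", "probably") %in% names(class_bands))) {
    stop("class_bands must name 'possibly' and 'probably' thresholds")
  }
  if (class_bands[["possibly"]] >= class_bands[["probably"]]) {
    stop("class bands must be strictly increasing")
  }
  structure(list(weights = weights,
                 multi_report_threshold = multi_report_threshold,
                 class_bands = class_bands,
                 functional_gate = isTRUE(functional_gate)),
            class = "mt_rubric")
}

#' Classify a variant from its evidence under a rubric
#'
#' Total score = sum of the weights of satisfied criteria; the class is read
#' off the score bands. With the functional gate on, a top-band score without
#' single-fibre or cybrid evidence is demoted to "probably".
#'
#' @param evidence [pathogenicity_evidence()].
#' @param rub [rubric()] (default: packaged rubric).
#' @return One of `"neutral"`, `"possibly"`, `"probably"`, `"definitely"`.
#' @export
classify_variant <- function(evidence, rub = load_rubric()) {
  stopifnot(inherits(evidence, "mt_evidence"), inherits(rub, "mt_rubric"))
  w <- rub$weights
  satisfied <- c(
    independent_reports =
      evidence$independent_reports >= rub$multi_report_threshold,
    evolutionary_conservation = evidence$evolutionary_conservation,
    heteroplasmy = evidence$heteroplasmy,
    segregation_with_phenotype = evidence$segregation_with_phenotype,
    biochemical_defect = evidence$biochemical_defect,
    single_fibre_evidence = evidence$single_fibre_evidence,
    cybrid_or_in_vitro_evidence = evidence$cybrid_or_in_vitro_evidence
  )
  score <- sum(w[names(satisfied)[satisfied]], na.rm = TRUE)
  gate_ok <- evidence$single_fibre_evidence ||
    evidence$cybrid_or_in_vitro_evidence
  if (score >= rub$class_bands[["probably"]]) {
    if (!rub$functional_gate || gate_ok) "definitely" else "probably"
  } else if (score >= rub$class_bands[["possibly"]]) {
    "possibly"
  } else {
    "neutral"
  }
}

#' Classify every variant in an evidence table
#'
#' @param evidence_df Data frame with one row per variant and the
#'   [pathogenicity_evidence()] fields as columns (plus any id columns).
#' @param rub [rubric()].
#' @return `evidence_df` with an added `class` column.
#' @export
classify_evidence_table <- function(evidence_df, rub = load_rubric()) {
  evidence_df$class <- vapply(seq_len(nrow(evidence_df)), function(i) {
    e <- pathogenicity_evidence(
      independent_reports = evidence_df$independent_reports[i],
      evolutionary_conservation = evidence_df$evolutionary_conservation[i],
      heteroplasmy = evidence_df$heteroplasmy[i],
      segregation_with_phenotype = evidence_df$segregation_with_phenotype[i],
      biochemical_defect = evidence_df$biochemical_defect[i],
      single_fibre_evidence = evidence_df$single_fibre_evidence[i],
      cybrid_or_in_vitro_evidence = evidence_df$cybrid_or_in_vitro_evidence[i]
    )
    classify_variant(e, rub)
  }, "")
  evidence_df
}
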