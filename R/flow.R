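FLOW_TAJIMA_LEVELS <- c("AllNeg", "AllPos", "AllNonSig", "NegNonsig",
                        "PosNonsig", "PosNeg", "PosNegNonsig",
                        "Mixed-undefined")

#' Tajima-step flow label for one transcript
#'
#' Reduces a transcript's per-population Tajima results to one of the eight
#' flow categories. Each population is scored `negative` (D < 0), `positive`
#' (D > 0) or `nonsignificant`; with `require_significance = TRUE` (default)
#' a signed call additionally needs `p <= alpha`. Populations with undefined
#' D (no segregating sites) count as nonsignificant; if every population is
#' undefined the transcript falls in the `Mixed-undefined` catch-all.
#'
#' @param d Numeric vector of Tajima's D, one per population (`NA` =
#'   undefined).
#' @param p Matching p-values.
#' @param require_significance Require `p <= alpha` for a signed call.
#' @param alpha Significance level.
#' @return A single label.
#' @export
#' @examples
#' tajima_flow_label(c(-2, -1.5, -2.2, -1.8), c(0.01, 0.04, 0.01, 0.02))
tajima_flow_label <- function(d, p, require_significance = TRUE,
                              alpha = 0.05) {
  if (length(d) != length(p) || length(d) < 1) {
    abort("need matched `d` and `p` for every population.")
  }
  if (all(is.na(d))) return("Mixed-undefined")
  sig <- if (require_significance) !is.na(p) & p <= alpha else !is.na(d)
  state <- dplyr::case_when(
    is.na(d) ~ "ns",
    sig & d < 0 ~ "neg",
    sig & d > 0 ~ "pos",
    .default = "ns"
  )
  n_neg <- sum(state == "neg")
  n_pos <- sum(state == "pos")
  n_ns <- sum(state == "ns")
  if (n_ns == length(d)) return("AllNonSig")
  if (n_neg == length(d)) return("AllNeg")
  if (n_pos == length(d)) return("AllPos")
  if (n_pos > 0 && n_neg > 0 && n_ns > 0) return("PosNegNonsig")
  if (n_pos > 0 && n_neg > 0) return("PosNeg")
  if (n_neg > 0) return("NegNonsig")
  "PosNonsig"
}

#' Cross-classify DETs over the four analysis steps
#'
#' Joins, per DET, the population assignment (step 1), the drift-null H
#' class (step 2: `H_lt` / `H_ge` around the selection threshold), the
#' transcript outlier label (step 3: `NC`, `noOL`, `Bal`, `Div`, `BalDiv`)
#' and the Tajima flow label (step 4), and tallies the path counts. DETs
#' missing a step's label fall back to `NC` (step 3), `Mixed-undefined`
#' (step 4) or `H_lt` (step 2) with a warning, so the table always
#' partitions the DET set.
#'
#' @param dets [assign_population_dets()] tibble.
#' @param h_results [h_test()] tibble (`transcript`, `selected`).
#' @param outlier_labels [transcript_outlier_labels()] tibble.
#' @param tajima_labels Tibble `transcript`, `tajima_label` (from
#'   [tajima_flow_label()] applied per transcript).
#' @return An object of class `"flow_table"`: list with `flow` (tibble
#'   `transcript`, `step1`, `step2`, `step3`, `step4`) and `paths` (tibble
#'   of distinct paths with `n`).
#' @export
build_flow <- function(dets, h_results, outlier_labels, tajima_labels) {
  det_only <- filter(dets, .data$det_population != "nonDET")
  flow <- det_only |>
    rename(step1 = "det_population") |>
    left_join(select(h_results, "transcript", "selected"),
              by = "transcript") |>
    left_join(outlier_labels, by = "transcript") |>
    left_join(tajima_labels, by = "transcript")
  n_miss <- sum(is.na(flow$selected)) + sum(is.na(flow$outlier_label)) +
    sum(is.na(flow$tajima_label))
  if (n_miss > 0) {
    warn(sprintf("%d missing step label(s); fallback categories assigned.",
                 n_miss))
  }
  flow <- flow |>
    mutate(
      step1 = paste0("Pop", .data$step1),
      step2 = dplyr::if_else(!is.na(.data$selected) & .data$selected,
                             "H_ge", "H_lt"),
      step3 = tidyr::replace_na(.data$outlier_label, "NC"),
      step4 = tidyr::replace_na(.data$tajima_label, "Mixed-undefined")
    ) |>
    select("transcript", "step1", "step2", "step3", "step4")
  paths <- flow |>
    dplyr::count(.data$step1, .data$step2, .data$step3, .data$step4,
                 name = "n") |>
    arrange(dplyr::desc(.data$n))
  structure(list(flow = flow, paths = paths), class = "flow_table")
}

#' @export
print.flow_table <- function(x, ...) {
  cat("<flow_table>\n")
  cat(sprintf("  %d DETs over %d distinct paths\n", nrow(x$flow),
              nrow(x$paths)))
  print(utils::head(x$paths, 10))
  invisible(x)
}

#' Write a flow table to CSV (alluvial-tool ready)
#'
#' @param flow_table A [build_flow()] result.
#' @param dir Output directory; writes `flow.csv`, `flow_paths.csv` and a
#'   JSON summary of per-step marginals.
#' @return `dir`, invisibly.
#' @export
write_flow <- function(flow_table, dir) {
  stopifnot(inherits(flow_table, "flow_table"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(flow_table$flow, file.path(dir, "flow.csv"))
  readr::write_csv(flow_table$paths, file.path(dir, "flow_paths.csv"))
  marg <- lapply(paste0("step", 1:4), function(s) {
    as.list(table(flow_table$flow[[s]]))
  })
  names(marg) <- paste0("step", 1:4)
  jsonlite::write_json(marg, file.path(dir, "flow_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
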