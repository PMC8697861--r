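#' Published PERV CRISPR-STOP guide set
#'
#' The packaged reference guide set against the three porcine endogenous
#' retrovirus subtypes (PERV-A/B/C): for each candidate guide, the gene
#' (gag/pol/env), direction relative to the coding strand, the stop-route
#' label, the full 23-nt target site (20-nt protospacer plus NGG PAM in
#' guide orientation), the published 16-19 bp editing window, the CDS
#' position of the site's leftmost forward-strand base, and the o/x
#' presence call in each subtype.  Used as ground truth for window
#' extraction and as ready-made protospacers for simulation.
#'
#' @return tibble with columns `gene`, `direction`, `stop_route`,
#'   `target_site`, `protospacer`, `pam`, `editing_window`, `position`,
#'   `perv_a`, `perv_b`, `perv_c`.
#' @export
perv_stop_guides <- function() {
  path <- system.file("extdata", "perv_stop_guides.tsv", package = "crisprstop",
                      mustWork = TRUE)
  readr::read_tsv(path, comment = "#", show_col_types = FALSE) |>
    mutate(protospacer = str_sub(.data$target_site, 1, 20),
           pam = str_sub(.data$target_site, 21, 23))
}
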