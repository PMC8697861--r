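#' Run the design -> matrix -> quantify pipeline on simulated inputs
#'
#' One-call assembly of the whole workflow at desk scale: generate a
#' diverged genome family with planted guide sites
#' ([make_provirus_family()]), design premature-stop guides for one gene in
#' every subtype ([design_stop_guides()]), intersect them across the panel
#' ([presence_matrix()]), then simulate an amplicon run over the first
#' all-present guide and quantify its window C-to-T substitution
#' ([simulate_amplicon_reads()], [quantify()]).  Every output is written to
#' `config$outdir` together with a machine-readable config echo (tool
#' version plus config hash), and reruns with the same config and seed are
#' byte-identical.
#'
#' @param config a list.  Required: `seed` (integer), `outdir`.  Optional
#'   (defaults in parentheses): `stages` (all of simulate, design, matrix,
#'   quantify), `gene` ("gag"), `n_subtypes` (3), `divergence` (0.05),
#'   `genes`, `conserved_sites` (see [make_provirus_family()]), `n_reads`
#'   (2000), `edit_fraction` (0.5), `error_rate` (0.001), `indel_fraction`
#'   (0.01), `flank` (80), `pam_pattern` ("NGG"), `window_from` (16),
#'   `window_to` (19).
#' @return a list with `status` (0), `files` (named vector of outputs) and
#'   `results` (the in-memory design table, presence matrix and
#'   substitution table for the stages run).
#' @export
run_pipeline <- function(config) {
  for (req in c("seed", "outdir")) {
    if (is.null(config[[req]])) {
      abort(paste0("config is missing required field: ", req),
            class = "crisprstop_usage_error")
    }
  }
  stages <- config$stages %||% c("simulate", "design", "matrix", "quantify")
  bad <- setdiff(stages, c("simulate", "design", "matrix", "quantify"))
  if (length(bad)) abort(paste0("unknown stage(s): ", paste(bad, collapse = ", ")),
                         class = "crisprstop_usage_error")
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  profile <- editor_profile(
    pam_pattern = config$pam_pattern %||% "NGG",
    window_from = config$window_from %||% 16L,
    window_to = config$window_to %||% 19L
  )
  gene <- config$gene %||% "gag"
  files <- c()
  results <- list()

  echo <- config
  echo$tool <- "crisprstop"
  echo$version <- as.character(utils::packageVersion("crisprstop"))
  echo$config_hash <- rlang::hash(config[order(names(config))])
  echo_path <- file.path(outdir, "config_echo.json")
  jsonlite::write_json(echo, echo_path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, null = "null")
  files["config"] <- echo_path

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (inherits(e, "crisprstop_usage_error")) stop(e)
      abort(paste0("stage '", name, "' failed: ", conditionMessage(e)),
            class = if (inherits(e, "crisprstop_format_error"))
              "crisprstop_format_error" else "crisprstop_computation_error")
    })
  }

  fam <- run_stage("simulate", make_provirus_family(
    seed = config$seed,
    n_subtypes = config$n_subtypes %||% 3,
    divergence = config$divergence %||% 0.05,
    genes = config$genes,
    conserved_sites = config$conserved_sites
  ))
  if ("simulate" %in% stages) {
    fa <- file.path(outdir, "genomes.fasta")
    write_fasta(tibble(id = fam$panel$genomes$label,
                       residues = fam$panel$genomes$residues), fa)
    readr::write_tsv(fam$panel$regions, file.path(outdir, "regions.tsv"))
    jsonlite::write_json(
      list(seed = fam$truth$seed, divergence = fam$truth$divergence,
           labels = fam$truth$labels,
           sites = fam$truth$sites),
      file.path(outdir, "sim_truth.json"), auto_unbox = TRUE, digits = NA)
    files["genomes"] <- fa
    files["regions"] <- file.path(outdir, "regions.tsv")
    files["sim_truth"] <- file.path(outdir, "sim_truth.json")
    results$panel <- fam$panel
    results$truth <- fam$truth
  }

  design <- NULL
  if (any(c("design", "matrix", "quantify") %in% stages)) {
    design <- run_stage("design", design_stop_guides(fam$panel, gene, profile))
    if ("design" %in% stages) {
      dp <- file.path(outdir, "design.tsv")
      readr::write_tsv(design |> select(-"target_c_offset") |>
                         mutate(creates_stop = TRUE), dp)
      files["design"] <- dp
      results$design <- design
    }
  }

  pm <- NULL
  if (any(c("matrix", "quantify") %in% stages)) {
    pm <- run_stage("matrix", presence_matrix(design, fam$panel,
                                              pam_pattern = profile$pam_pattern))
    if ("matrix" %in% stages) {
      mp <- file.path(outdir, "presence_matrix.tsv")
      readr::write_tsv(as_tibble(pm), mp)
      files["matrix"] <- mp
      results$matrix <- pm
    }
  }

  if ("quantify" %in% stages) {
    hit <- as_tibble(pm) |> filter(.data$all_present)
    if (nrow(hit) == 0) {
      abort("stage 'quantify' failed: no all-present guide to quantify",
            class = "crisprstop_computation_error")
    }
    g <- hit[1, ]
    region <- fam$panel$regions |>
      filter(.data$label == fam$panel$genomes$label[1], .data$gene == .env$gene)
    genome1 <- fam$panel$genomes$residues[1]
    site_start_g <- region$start[1] + g$cds_position - 1L
    site_end_g <- site_start_g + profile$protospacer_length +
      nchar(profile$pam_pattern) - 1L
    flank <- config$flank %||% 80L
    amp_start <- max(1L, site_start_g - flank)
    amp_end <- min(nchar(genome1), site_end_g + flank)
    amp <- str_sub(genome1, amp_start, amp_end)
    guide_start <- if (g$direction == "+") site_start_g - amp_start + 1L
                   else site_end_g - amp_start + 1L
    ref <- run_stage("quantify", amplicon_reference(
      amp, g$protospacer, guide_start, g$direction, profile,
      target_c_offset = g$target_c_offset
    ))
    sim <- run_stage("quantify", simulate_amplicon_reads(
      ref, n_reads = config$n_reads %||% 2000,
      edit_fraction = config$edit_fraction %||% 0.5,
      seed = config$seed + 1L,
      error_rate = config$error_rate %||% 0.001,
      indel_fraction = config$indel_fraction %||% 0.01,
      dir = outdir, prefix = "amplicon"
    ))
    tab <- run_stage("quantify", quantify(sim$r1, ref))
    readr::write_tsv(tidy(tab), file.path(outdir, "substitution_positions.tsv"))
    readr::write_tsv(tab$window, file.path(outdir, "substitution_window.tsv"))
    haps <- top_haplotypes(tab)
    writeLines(c(
      sprintf("# top read haplotypes over the guide region (of %d aligned reads)",
              tab$n_reads_aligned),
      sprintf("%-40s %8s %8s %s", "haplotype", "count", "percent", "ref"),
      sprintf("%-40s %8d %8s %s", haps$haplotype, haps$count,
              fmt_pct(haps$percent), if_else(haps$is_reference, "*", ""))
    ), file.path(outdir, "haplotypes.txt"))
    summary <- c(list(config_hash = echo$config_hash, version = echo$version,
                      gene = gene, guide = g$protospacer, direction = g$direction,
                      injected_edit_fraction = config$edit_fraction %||% 0.5),
                 as.list(glance(tab)),
                 list(window_c_to_t_percent_rounded =
                        round_half_up(tab$window_c_to_t_percent, 2)),
                 tab$run)
    jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    files["reads"] <- sim$r1
    files["positions"] <- file.path(outdir, "substitution_positions.tsv")
    files["window"] <- file.path(outdir, "substitution_window.tsv")
    files["haplotypes"] <- file.path(outdir, "haplotypes.txt")
    files["summary"] <- file.path(outdir, "summary.json")
    results$substitution <- tab
  }

  list(status = 0L, files = files, results = results)
}
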