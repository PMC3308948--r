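parse_hours <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  x <- trimws(as.character(x))
  hhmm <- grepl("^\\d{1,3}:\\d{2}$", x)
  out <- suppressWarnings(as.numeric(x))
  if (any(hhmm)) {
    parts <- strsplit(x[hhmm], ":", fixed = TRUE)
    out[hhmm] <- vapply(parts, function(p) {
      as.numeric(p[1]) + as.numeric(p[2]) / 60
    }, numeric(1))
  }
  if (anyNA(out)) {
    stop("unparseable time value(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "), call. = FALSE)
  }
  out
}

guess_delim <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) return(",")
  if (grepl("\\.(tsv|tab|txt)$", path, ignore.case = TRUE)) return("\t")
  first <- readLines(path, n = 25)
  first <- first[!startsWith(first, "#")][1]
  if (grepl("\t", first)) "\t" else ","
}

#' Read a plate-reader growth table
#'
#' Reads hourly OD600 readings in either of the two common shapes:
#' * `layout = "long"`: one reading per row, columns `well` (or the full
#'   identifier set `experiment`/`lineage`/`clone`/`replicate`), `time`, `od`;
#' * `layout = "wide"`: one row per time point, first column `time`, one
#'   column per well.
#'
#' Time may be decimal hours or `HH:MM` (converted on read). Comma and tab
#' delimiters are auto-detected from the extension or content; lines
#' starting with `#` are ignored. Duplicate `(well, time)` entries and
#' missing OD values are reported as errors naming the offending file lines;
#' a non-increasing time column in a wide file is likewise an error.
#'
#' @param path Delimited text file.
#' @param layout `"long"` or `"wide"`.
#' @param metadata Optional data frame mapping `well` to `experiment`,
#'   `lineage`, `clone`, `replicate`. Wells absent from the map are skipped
#'   with a warning.
#' @return A long tibble of validated growth curves: identifier columns plus
#'   `time` (hours, sorted within well) and `od`.
#' @export
read_plate_table <- function(path, layout = c("long", "wide"),
                             metadata = NULL) {
  layout <- match.arg(layout)
  delim <- guess_delim(path)
  raw <- readr::read_delim(path, delim = delim, comment = "#",
                           show_col_types = FALSE, progress = FALSE,
                           col_types = readr::cols(.default = "c"))
  # line number of each data row in the file (header + comment offset)
  all_lines <- readLines(path)
  data_line <- which(!startsWith(all_lines, "#") & nzchar(all_lines))[-1]

  if (layout == "wide") {
    tvals <- parse_hours(raw[[1]])
    if (any(diff(tvals) <= 0)) {
      bad <- which(diff(tvals) <= 0)[1] + 1
      stop("wide table time column is not strictly increasing at line ",
           data_line[bad], call. = FALSE)
    }
    long <- tidyr::pivot_longer(
      dplyr::mutate(raw[-1], time = tvals, .line = data_line),
      cols = -dplyr::all_of(c("time", ".line")),
      names_to = "well", values_to = "od")
  } else {
    if (!all(c("time", "od") %in% names(raw))) {
      stop("long table must have `time` and `od` columns", call. = FALSE)
    }
    long <- dplyr::mutate(raw, time = parse_hours(.data$time),
                          .line = data_line)
  }

  long$od <- suppressWarnings(as.numeric(long$od))
  if (anyNA(long$od)) {
    stop("missing or non-numeric OD at line(s) ",
         paste(utils::head(long$.line[is.na(long$od)], 10), collapse = ", "),
         call. = FALSE)
  }
  if (any(long$od < 0)) {
    stop("negative OD at line(s) ",
         paste(utils::head(long$.line[long$od < 0], 10), collapse = ", "),
         call. = FALSE)
  }

  id_cols <- intersect(c("well", "experiment", "lineage", "clone",
                         "replicate"), names(long))
  if (length(id_cols) == 0) {
    stop("no well/identifier columns found", call. = FALSE)
  }
  key <- do.call(paste, c(long[id_cols], sep = "\r"))
  dup <- duplicated(cbind(key, long$time)) |
    duplicated(cbind(key, long$time), fromLast = TRUE)
  if (any(dup & duplicated(cbind(key, long$time)))) {
    lines <- long$.line[duplicated(cbind(key, long$time))]
    stop("duplicated (well, time) reading(s) at line(s) ",
         paste(utils::head(lines, 10), collapse = ", "), call. = FALSE)
  }

  if (!is.null(metadata)) {
    if (!"well" %in% names(long)) {
      stop("`metadata` given but the table has no `well` column",
           call. = FALSE)
    }
    metadata <- dplyr::as_tibble(metadata)
    unmapped <- setdiff(unique(long$well), metadata$well)
    if (length(unmapped) > 0) {
      warning("skipping ", length(unmapped), " unmapped well(s): ",
              paste(utils::head(unmapped, 10), collapse = ", "),
              call. = FALSE)
      long <- long[long$well %in% metadata$well, ]
    }
    long <- dplyr::inner_join(long, metadata, by = "well")
    id_cols <- intersect(c("experiment", "lineage", "clone", "replicate"),
                         names(long))
  }
  out <- dplyr::select(long, dplyr::all_of(id_cols), "time", "od")
  dplyr::arrange(out, dplyr::across(dplyr::all_of(id_cols)), .data$time)
}

#' Write a growth-curve table
#'
#' Long CSV, full double precision (readable back losslessly by
#' [read_plate_table()]).
#'
#' @param curves Long tibble as produced by [simulate_plate()] or
#'   [read_plate_table()].
#' @param path Output file ending in `.csv` or `.tsv`.
#' @return `path`, invisibly.
#' @export
write_plate_table <- function(curves, path) {
  if (grepl("\\.tsv$", path)) readr::write_tsv(curves, path)
  else readr::write_csv(curves, path)
  invisible(path)
}

#' Run the whole fitness-analysis pipeline
#'
#' Fit -> summarise -> contrast -> (optionally) sequence covariates ->
#' regress, in one call. The stages are the exported verbs
#' ([fit_growth_curves()], [summarise_fitness()], [protein_divergence()],
#' [cai()], [regress_fitness_on_covariate()]); this wrapper wires them
#' together, records every analysis setting in force, and (optionally)
#' writes the result tables, figures and a log under `out_dir`.
#'
#' @param config Named list:
#'   * `curves` (long tibble) or `plate_table` (+ optional `layout`,
#'     `metadata`) — the growth data;
#'   * `control` — control lineage id (required);
#'   * `m`, `min_dynamic_range`, `alpha` — analysis settings (defaults 0.5,
#'     0.05 OD, 0.001);
#'   * `protein_fasta` — aligned protein FASTA (or named vector) for
#'     divergence covariates; `reference` — id of the control's sequence;
#'   * `coding_fasta` — unaligned coding DNA FASTA (or named vector) for
#'     CAI; `w_floor` — zero-count floor (default 0.01);
#'   * sequence names (after stripping the reference) must equal lineage
#'     ids, or supply `covariate_map`, a data frame `lineage`/`seq_id`;
#'   * `out_dir` — directory for `fits.tsv`, `summary.tsv`,
#'     `covariates.tsv`, `regressions.tsv`, `log.txt`; `write_plots = TRUE`
#'     adds the figure set as PDFs.
#' @return A `platefit_report`: list with `fits`, `summary`, `covariates`
#'   (or `NULL`), `regressions` (or `NULL`) and `settings`.
#' @export
run_pipeline <- function(config) {
  stopifnot(is.list(config))
  if (is.null(config$control)) stop("`config$control` is required", call. = FALSE)
  m <- config$m %||% 0.5
  alpha <- config$alpha %||% 0.001
  mdr <- config$min_dynamic_range %||% 0.05
  w_floor <- config$w_floor %||% 0.01

  curves <- if (!is.null(config$curves)) {
    dplyr::as_tibble(config$curves)
  } else if (!is.null(config$plate_table)) {
    read_plate_table(config$plate_table,
                     layout = config$layout %||% "long",
                     metadata = config$metadata)
  } else {
    stop("config must provide `curves` or `plate_table`", call. = FALSE)
  }

  fits <- fit_growth_curves(curves, m = m, min_dynamic_range = mdr)
  summary <- summarise_fitness(fits, control = config$control, alpha = alpha)

  covariates <- NULL
  if (!is.null(config$protein_fasta)) {
    div <- protein_divergence(config$protein_fasta,
                              reference = config$reference %||% NULL)
    covariates <- dplyr::rename(div, seq_id = "seq_b")
  }
  if (!is.null(config$coding_fasta)) {
    cai_tab <- cai(config$coding_fasta, w_floor = w_floor)
    cai_tab <- dplyr::select(cai_tab, seq_id = "id", "cai")
    covariates <- if (is.null(covariates)) cai_tab
                  else dplyr::full_join(covariates, cai_tab, by = "seq_id")
  }

  regressions <- NULL
  if (!is.null(covariates)) {
    cov <- covariates
    if (!is.null(config$covariate_map)) {
      cov <- dplyr::inner_join(cov, dplyr::as_tibble(config$covariate_map),
                               by = "seq_id")
    } else {
      cov$lineage <- cov$seq_id
    }
    merged <- dplyr::inner_join(
      dplyr::filter(summary, .data$lineage != config$control),
      cov, by = "lineage")
    regressions <- purrr::list_rbind(lapply(
      intersect(c("jtt_distance", "p_distance", "cai"), names(merged)),
      function(cv) {
        purrr::list_rbind(lapply(
          c("relative_mu_max", "relative_tti"), function(resp) {
            res <- try(regress_fitness_on_covariate(x = merged[[cv]],
                                                    y = merged[[resp]]),
                       silent = TRUE)
            if (inherits(res, "try-error")) return(NULL)
            dplyr::mutate(res, covariate = cv, response = resp, .before = 1)
          }))
      }))
    covariates <- cov
  }

  settings <- list(
    m = m, alpha = alpha, min_dynamic_range = mdr, w_floor = w_floor,
    control = config$control,
    gap_policy = "complete deletion over each pair",
    lineage_test = "Welch two-sample t-test, two-sided",
    multiple_testing = "none (per-experiment contrasts reported as-is)",
    package_version = as.character(utils::packageVersion("platefit")))

  report <- structure(list(fits = fits, summary = summary,
                           covariates = covariates,
                           regressions = regressions, settings = settings),
                      class = "platefit_report")
  if (!is.null(config$out_dir)) {
    write_report(report, config$out_dir,
                 write_plots = isTRUE(config$write_plots), curves = curves)
  }
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_report <- function(report, out_dir, write_plots = FALSE,
                         curves = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(report$fits, file.path(out_dir, "fits.tsv"))
  readr::write_tsv(tibble::as_tibble(report$summary),
                   file.path(out_dir, "summary.tsv"))
  if (!is.null(report$covariates)) {
    readr::write_tsv(tidyr::unnest(report$covariates,
                                   dplyr::any_of("codon_counts")),
                     file.path(out_dir, "covariates.tsv"))
  }
  if (!is.null(report$regressions)) {
    readr::write_tsv(report$regressions,
                     file.path(out_dir, "regressions.tsv"))
  }
  s <- report$settings
  writeLines(c(
    "platefit pipeline log",
    sprintf("package version: %s", s$package_version),
    sprintf("Richards shape parameter m (fixed): %s", format(s$m)),
    sprintf("no-growth minimum dynamic range: %s OD", format(s$min_dynamic_range)),
    sprintf("control lineage: %s", s$control),
    sprintf("lineage contrast: %s at alpha = %s", s$lineage_test,
            format(s$alpha)),
    sprintf("multiple testing: %s", s$multiple_testing),
    sprintf("alignment gap policy: %s", s$gap_policy),
    sprintf("CAI zero-count w floor: %s", format(s$w_floor))),
    file.path(out_dir, "log.txt"))
  if (write_plots) {
    if (!is.null(curves)) {
      ggplot2::ggsave(file.path(out_dir, "growth_curves.pdf"),
                      plot_growth_curves(curves), width = 7, height = 5)
    }
    ggplot2::ggsave(file.path(out_dir, "relative_fitness.pdf"),
                    ggplot2::autoplot(report$summary), width = 7, height = 5)
    if (!is.null(report$covariates)) {
      merged <- dplyr::inner_join(
        dplyr::filter(tibble::as_tibble(report$summary),
                      .data$lineage != report$settings$control),
        report$covariates, by = "lineage")
      for (cv in intersect(c("jtt_distance", "cai"), names(merged))) {
        ggplot2::ggsave(
          file.path(out_dir, paste0("fitness_vs_", cv, ".pdf")),
          plot_fitness_vs_covariate(merged, covariate = cv),
          width = 7, height = 4)
      }
    }
  }
  invisible(out_dir)
}

#' @export
print.platefit_report <- function(x, ...) {
  cat("platefit pipeline report\n")
  cat("  wells fitted:", nrow(x$fits),
      sprintf("(%d converged)\n", sum(x$fits$converged)))
  cat("  lineage summary:\n")
  print(tibble::as_tibble(x$summary), n = 12)
  if (!is.null(x$regressions)) {
    cat("  covariate regressions:\n")
    print(x$regressions)
  }
  invisible(x)
}
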