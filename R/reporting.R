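# Comparative outputs: the ordered confusion-matrix heat map, flat TSV
# reports (summary metrics, per-bin tables, genome recovery, rankings),
# plot-data TSVs, rendered figures and a static HTML summary page.
#
# All tables are written with a fixed column order, byte-order sorting and
# 6 significant digits, so reruns on identical input are byte-identical.

#' Ordered bin-by-genome heat-map matrix
#'
#' Arranges the contingency table so that true positives concentrate on
#' the leading diagonal: bins (rows) are sorted by their true positives
#' descending (ties: larger bin first, then label), genomes (columns)
#' follow the mapped genome of each sorted bin in first-occurrence order,
#' with genomes mapped by no bin appended in descending size. A terminal
#' `unassigned` row holds the unassigned base pairs of every genome, so
#' row sums equal bin sizes, column sums equal genome sizes, and the grand
#' total equals the gold-standard base pairs in scope.
#'
#' @param ct A `bin_contingency`.
#' @param mapping A `bin_genome_mapping` built from `ct` (the majority
#'   criterion is the conventional choice for display).
#' @return A numeric matrix of bp counts with class `heatmap_matrix`;
#'   rows are bin ids plus `"unassigned"`, columns are genome ids.
#' @export
heatmap_matrix <- function(ct, mapping = map_bins_majority(ct)) {
  stopifnot(inherits(ct, "bin_contingency"), inherits(mapping, "bin_genome_mapping"))
  bins <- names(mapping$mapped_genome)
  ord <- order(-mapping$tp_bp, -ct$bin_totals_bp[bins], bins, method = "radix")
  sorted_bins <- bins[ord]
  mapped_seq <- unname(mapping$mapped_genome[sorted_bins])
  genomes_mapped <- mapped_seq[!duplicated(mapped_seq)]
  rest <- setdiff(colnames(ct$cells_bp), genomes_mapped)
  rest <- rest[order(-ct$genome_sizes[rest], rest, method = "radix")]
  col_order <- c(genomes_mapped, rest)
  m <- rbind(ct$cells_bp[sorted_bins, col_order, drop = FALSE],
             unassigned = ct$unassigned_per_genome_bp[col_order])
  rownames(m) <- c(sorted_bins, "unassigned")
  class(m) <- c("heatmap_matrix", class(m))
  m
}

fmt_num <- function(x) {
  ifelse(is.na(x), "NA",
         formatC(signif(x, 6), format = "g", digits = 6, flag = "#"))
}

write_tsv_lines <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

df_to_tsv <- function(df, path, comment = NULL) {
  body <- do.call(paste, c(lapply(df, function(col) {
    if (is.numeric(col) && !is.integer(col)) fmt_num(col) else as.character(col)
  }), sep = "\t"))
  lines <- c(if (!is.null(comment)) paste0("# ", comment),
             paste(names(df), collapse = "\t"), body)
  write_tsv_lines(lines, path)
}

summary_row <- function(s) {
  data.frame(
    label = s$label,
    n_bins = s$n_bins,
    n_bins_truncated = s$n_bins_truncated,
    n_genomes = s$n_genomes,
    avg_purity = s$avg_purity,
    std_error_purity = s$std_error_purity,
    avg_contamination = s$avg_contamination,
    truncated_avg_purity = s$truncated_avg_purity,
    avg_completeness = s$avg_completeness,
    std_error_completeness = s$std_error_completeness,
    avg_purity_bp = s$avg_purity_bp,
    avg_completeness_bp = s$avg_completeness_bp,
    accuracy = s$accuracy,
    ari_bp = s$ari_bp,
    ari_seq = s$ari_seq,
    pct_assigned_bp = s$pct_assigned_bp,
    pct_assigned_seq = s$pct_assigned_seq,
    stringsAsFactors = FALSE
  )
}

safe_name <- function(x) gsub("[^A-Za-z0-9._-]+", "_", x)

#' Write the flat-file comparative reports
#'
#' Emits, into `outdir`: `summary.tsv` (one row per binning, one column
#' per metric), `bins/<label>.tsv` (per-bin id, mapped genome, size,
#' purity, completeness, contamination), `recovery.tsv` (genomes
#' recovered per binner at each contamination x completeness threshold
#' pair) and `rankings.tsv` (one section per ranking criterion). Output
#' is deterministic.
#'
#' @param summaries List of `bin_assessment` objects.
#' @param outdir Output directory, created if needed.
#' @return Character vector of written paths, invisibly.
#' @export
write_flat_reports <- function(summaries, outdir) {
  if (length(summaries) == 0L) stop("no summaries to report", call. = FALSE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outdir, "bins"), showWarnings = FALSE)
  written <- character()

  sm <- do.call(rbind, lapply(summaries, summary_row))
  p <- file.path(outdir, "summary.tsv")
  df_to_tsv(sm, p, comment = "assessment summary: one row per binning")
  written <- c(written, p)

  for (s in summaries) {
    p <- file.path(outdir, "bins", paste0(safe_name(s$label), ".tsv"))
    df_to_tsv(s$bin_metrics, p,
              comment = sprintf("per-bin metrics for '%s' (%s mapping)",
                                s$label, s$mapping_criterion))
    written <- c(written, p)
  }

  rec_rows <- list()
  for (s in summaries) {
    rc <- s$recovery_counts
    for (i in seq_len(nrow(rc))) {
      row <- data.frame(label = s$label, contamination = rownames(rc)[i],
                        stringsAsFactors = FALSE)
      for (j in seq_len(ncol(rc))) row[[colnames(rc)[j]]] <- rc[i, j]
      rec_rows[[length(rec_rows) + 1L]] <- row
    }
  }
  p <- file.path(outdir, "recovery.tsv")
  df_to_tsv(do.call(rbind, rec_rows), p,
            comment = "genomes recovered below contamination and above completeness thresholds")
  written <- c(written, p)

  rank_lines <- "# binning rankings (descending; ties broken by label)"
  for (crit in c("purity", "completeness", "purity_plus_completeness")) {
    rk <- rank_binnings(summaries, crit)
    rank_lines <- c(rank_lines, paste0("# criterion: ", crit),
                    "rank\tlabel\tvalue",
                    paste(rk$rank, rk$label, fmt_num(rk$value), sep = "\t"))
  }
  p <- file.path(outdir, "rankings.tsv")
  write_tsv_lines(rank_lines, p)
  written <- c(written, p)
  invisible(written)
}

heatmap_to_tsv <- function(hm, path) {
  lines <- c("# bin-by-genome heat map (bp); last row = unassigned bp per genome",
             paste(c("bin_id", colnames(hm)), collapse = "\t"),
             vapply(seq_len(nrow(hm)), function(i) {
               paste(c(rownames(hm)[i],
                       format(hm[i, ], trim = TRUE, scientific = FALSE)),
                     collapse = "\t")
             }, character(1L)))
  write_tsv_lines(lines, path)
}

plot_data_frames <- function(summaries) {
  labels <- vapply(summaries, `[[`, character(1L), "label")
  list(
    purity_completeness = data.frame(
      label = labels,
      truncated_avg_purity = vapply(summaries, `[[`, numeric(1L), "truncated_avg_purity"),
      std_error_purity = vapply(summaries, `[[`, numeric(1L), "std_error_purity"),
      avg_completeness = vapply(summaries, `[[`, numeric(1L), "avg_completeness"),
      std_error_completeness = vapply(summaries, `[[`, numeric(1L), "std_error_completeness"),
      stringsAsFactors = FALSE),
    purity_completeness_bp = data.frame(
      label = labels,
      avg_purity_bp = vapply(summaries, `[[`, numeric(1L), "avg_purity_bp"),
      avg_completeness_bp = vapply(summaries, `[[`, numeric(1L), "avg_completeness_bp"),
      stringsAsFactors = FALSE),
    ari_vs_assigned = data.frame(
      label = labels,
      ari_bp = vapply(summaries, `[[`, numeric(1L), "ari_bp"),
      pct_assigned_bp = vapply(summaries, `[[`, numeric(1L), "pct_assigned_bp"),
      stringsAsFactors = FALSE),
    per_bin = do.call(rbind, lapply(summaries, function(s) {
      data.frame(label = s$label, bin_id = s$bin_metrics$bin_id,
                 purity = s$bin_metrics$purity,
                 completeness = s$bin_metrics$completeness,
                 stringsAsFactors = FALSE)
    }))
  )
}

render_figures <- function(pd, heatmaps, plotdir) {
  ok <- TRUE
  save_plot <- function(plot, path, width = 6, height = 5) {
    tryCatch({
      ggplot2::ggsave(path, plot = plot, width = width, height = height, dpi = 120)
      TRUE
    }, error = function(e) {
      warning(sprintf("could not render %s: %s", basename(path), conditionMessage(e)),
              call. = FALSE)
      FALSE
    })
  }
  aes <- ggplot2::aes
  p_a <- ggplot2::ggplot(pd$purity_completeness,
                         aes(x = .data$truncated_avg_purity, y = .data$avg_completeness,
                             colour = .data$label)) +
    ggplot2::geom_errorbar(aes(ymin = .data$avg_completeness - .data$std_error_completeness,
                               ymax = .data$avg_completeness + .data$std_error_completeness),
                           width = 0) +
    ggplot2::geom_errorbarh(aes(xmin = .data$truncated_avg_purity - .data$std_error_purity,
                                xmax = .data$truncated_avg_purity + .data$std_error_purity),
                            height = 0) +
    ggplot2::geom_point(size = 3) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Average purity per bin", y = "Average completeness per genome") +
    ggplot2::theme_bw()
  ok <- save_plot(p_a, file.path(plotdir, "purity_completeness.png")) && ok

  p_b <- ggplot2::ggplot(pd$purity_completeness_bp,
                         aes(x = .data$avg_purity_bp, y = .data$avg_completeness_bp,
                             colour = .data$label)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Average purity per bp", y = "Average completeness per bp") +
    ggplot2::theme_bw()
  ok <- save_plot(p_b, file.path(plotdir, "purity_completeness_bp.png")) && ok

  p_c <- ggplot2::ggplot(pd$ari_vs_assigned,
                         aes(x = .data$ari_bp, y = .data$pct_assigned_bp,
                             colour = .data$label)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Adjusted Rand index (bp, assigned portion)",
                  y = "Fraction of sample assigned (bp)") +
    ggplot2::theme_bw()
  ok <- save_plot(p_c, file.path(plotdir, "ari_vs_assigned.png")) && ok

  p_d <- ggplot2::ggplot(pd$per_bin, aes(x = .data$label, y = .data$purity)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "Purity per bin") + ggplot2::theme_bw()
  ok <- save_plot(p_d, file.path(plotdir, "purity_boxplot.png")) && ok

  p_e <- ggplot2::ggplot(pd$per_bin, aes(x = .data$label, y = .data$completeness)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "Completeness per bin") + ggplot2::theme_bw()
  ok <- save_plot(p_e, file.path(plotdir, "completeness_boxplot.png")) && ok

  for (label in names(heatmaps)) {
    hm <- heatmaps[[label]]
    df <- data.frame(
      bin = factor(rep(rownames(hm), ncol(hm)), levels = rev(rownames(hm))),
      genome = factor(rep(colnames(hm), each = nrow(hm)), levels = colnames(hm)),
      bp = as.vector(hm)
    )
    p_h <- ggplot2::ggplot(df, aes(x = .data$genome, y = .data$bin,
                                   fill = log10(.data$bp + 1))) +
      ggplot2::geom_tile() +
      ggplot2::scale_fill_viridis_c(name = "log10(bp + 1)") +
      ggplot2::labs(x = "Genome", y = "Predicted bin", title = label) +
      ggplot2::theme_bw() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5,
                                                         hjust = 1, size = 6),
                     axis.text.y = ggplot2::element_text(size = 6))
    ok <- save_plot(p_h, file.path(plotdir, paste0("heatmap_", safe_name(label), ".png"))) && ok
  }
  ok
}

html_table <- function(df) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", as.character(x), fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  cells <- lapply(df, function(col) {
    if (is.numeric(col) && !is.integer(col)) fmt_num(col) else esc(col)
  })
  rows <- do.call(paste0, c(list("<tr>"),
                            lapply(cells, function(x) paste0("<td>", x, "</td>")),
                            list("</tr>")))
  paste0("<table border='1' cellspacing='0' cellpadding='4'>\n<tr>",
         paste0("<th>", esc(names(df)), "</th>", collapse = ""), "</tr>\n",
         paste(rows, collapse = "\n"), "\n</table>")
}

embed_image <- function(path) {
  if (!file.exists(path)) return("")
  uri <- if (requireNamespace("jsonlite", quietly = TRUE)) {
    paste0("data:image/png;base64,",
           jsonlite::base64_enc(readBin(path, "raw", file.info(path)$size)))
  } else {
    basename(path)
  }
  sprintf("<p><img src='%s' style='max-width:720px'/></p>", uri)
}

#' Render the comparative summary: plot data, figures and HTML page
#'
#' Writes, into `outdir`: `plots/*.tsv` with the numeric series behind
#' each figure (purity vs completeness with standard errors, bp-weighted
#' purity vs completeness, ARI vs fraction assigned, per-bin values for
#' the box plots), the corresponding PNG figures, one heat-map TSV and
#' PNG per binning under `heatmaps/`, and a static self-contained
#' `index.html` embedding the tables and images. When no plotting device
#' is available the figures are skipped with a warning but every TSV is
#' still written.
#'
#' @param summaries List of `bin_assessment` objects.
#' @param heatmaps Optional named list of [heatmap_matrix()] objects, one
#'   per summary label; computed from the summaries when omitted.
#' @param outdir Output directory.
#' @param render_images Set `FALSE` to skip PNG rendering.
#' @return Invisibly, `TRUE` if all requested figures rendered.
#' @export
render_summary <- function(summaries, heatmaps = NULL, outdir,
                           render_images = TRUE) {
  if (length(summaries) == 0L) stop("no summaries to render", call. = FALSE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  plotdir <- file.path(outdir, "plots")
  hmdir <- file.path(outdir, "heatmaps")
  dir.create(plotdir, showWarnings = FALSE)
  dir.create(hmdir, showWarnings = FALSE)

  if (is.null(heatmaps)) {
    heatmaps <- lapply(summaries, function(s) heatmap_matrix(s$contingency, s$mapping))
    names(heatmaps) <- vapply(summaries, `[[`, character(1L), "label")
  }
  pd <- plot_data_frames(summaries)
  df_to_tsv(pd$purity_completeness,
            file.path(plotdir, "purity_completeness_data.tsv"),
            comment = "avg purity per bin (truncated) vs avg completeness per genome, with standard errors")
  df_to_tsv(pd$purity_completeness_bp,
            file.path(plotdir, "purity_completeness_bp_data.tsv"),
            comment = "avg purity per bp vs avg completeness per bp")
  df_to_tsv(pd$ari_vs_assigned,
            file.path(plotdir, "ari_vs_assigned_data.tsv"),
            comment = "adjusted Rand index (bp) vs fraction of sample assigned")
  df_to_tsv(pd$per_bin, file.path(plotdir, "per_bin_data.tsv"),
            comment = "per-bin purity and completeness (box plot series)")
  for (label in names(heatmaps)) {
    heatmap_to_tsv(heatmaps[[label]],
                   file.path(hmdir, paste0(safe_name(label), ".tsv")))
  }

  all_rendered <- TRUE
  if (render_images) {
    all_rendered <- render_figures(pd, heatmaps, plotdir)
  }

  sm <- do.call(rbind, lapply(summaries, summary_row))
  figs <- c("purity_completeness.png", "purity_completeness_bp.png",
            "ari_vs_assigned.png", "purity_boxplot.png", "completeness_boxplot.png",
            paste0("heatmap_", safe_name(names(heatmaps)), ".png"))
  html <- c(
    "<!DOCTYPE html><html><head><meta charset='utf-8'/>",
    "<title>Genome binning assessment</title></head><body>",
    "<h1>Genome binning assessment</h1>",
    "<h2>Summary metrics</h2>", html_table(sm),
    "<h2>Figures</h2>",
    unlist(lapply(file.path(plotdir, figs), embed_image)),
    "</body></html>"
  )
  write_tsv_lines(html, file.path(outdir, "index.html"))
  invisible(all_rendered)
}
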