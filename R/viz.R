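# Summary figures and reports. SVG is the canonical output: it is emitted
# directly as text with fixed metrics, so identical inputs produce
# byte-identical files that can be diffed in tests. PNG rendering goes
# through the standard graphics device and is provided for convenience.

#' Default risk-level colours
#'
#' Traffic-light convention: red for high risk, yellow for unclear, green
#' for low, blue for "no information".
#'
#' @return Named character vector of hex colours over [risk_levels()].
#' @export
risk_colors <- function() {
  c(low = "#02a550", unclear = "#f7d842", high = "#d7191c",
    no_information = "#4575b4")
}

#' Figure specification
#'
#' @param kind `"summary_bars"` (one stacked bar per domain plus overall)
#'   or `"traffic_light"` (study-by-domain matrix).
#' @param color_map named colours covering all four risk levels.
#' @param output_format `"svg"` (canonical, deterministic) or `"png"`.
#' @return An object of class `figure_spec`.
#' @export
figure_spec <- function(kind = c("summary_bars", "traffic_light"),
                        color_map = risk_colors(),
                        output_format = c("svg", "png")) {
  kind <- match.arg(kind)
  output_format <- match.arg(output_format)
  if (!all(risk_levels() %in% names(color_map))) {
    stop("color_map must cover all four risk levels", call. = FALSE)
  }
  structure(list(kind = kind, color_map = color_map,
                 output_format = output_format), class = "figure_spec")
}

# minimal deterministic SVG emitter ------------------------------------------

svg_open <- function(width, height) {
  c('<?xml version="1.0" encoding="UTF-8"?>',
    sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" width="%d" ',
                   'height="%d" viewBox="0 0 %d %d" ',
                   'font-family="Helvetica, Arial, sans-serif">'),
            width, height, width, height))
}

svg_rect <- function(x, y, w, h, fill) {
  sprintf('<rect x="%.2f" y="%.2f" width="%.2f" height="%.2f" fill="%s" stroke="#ffffff" stroke-width="1"/>',
          x, y, w, h, fill)
}

svg_text <- function(x, y, s, size = 12, anchor = "start") {
  sprintf('<text x="%.2f" y="%.2f" font-size="%d" text-anchor="%s">%s</text>',
          x, y, size, anchor, xml_escape(s))
}

xml_escape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  gsub(">", "&gt;", s, fixed = TRUE)
}

write_svg <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(lines, "</svg>"), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

svg_legend <- function(x, y, color_map) {
  labels <- c(low = "Low", unclear = "Unclear", high = "High",
              no_information = "No information")
  out <- character(0)
  for (lev in names(labels)) {
    out <- c(out, svg_rect(x, y - 10, 14, 14, color_map[[lev]]),
             svg_text(x + 20, y + 1, labels[[lev]], size = 11))
    x <- x + 26 + 7.5 * nchar(labels[[lev]])
  }
  out
}

# renderers --------------------------------------------------------------------

#' Render the stacked-bar risk-of-bias summary figure
#'
#' One horizontal stacked bar per domain (D1-D4) plus one for the overall
#' rating; segment widths are proportional to the percentage of studies at
#' each risk level, in the order low, unclear, high.
#'
#' @param summary an `ndd_summary` (see [summarize_cohort()]).
#' @param path output file path.
#' @param spec a [figure_spec()].
#' @return `path`, invisibly.
#' @export
render_summary_bars <- function(summary, path,
                                spec = figure_spec("summary_bars")) {
  stopifnot(inherits(summary, "ndd_summary"))
  width <- 640L; height <- 230L
  bar_x <- 90; bar_w <- 500; bar_h <- 24; gap <- 34; top <- 30
  rows <- rbind(summary$domain_distribution,
                Overall = summary$overall_distribution)
  rownames(rows)[1:4] <- paste0("D", 1:4)
  lines <- svg_open(width, height)
  y <- top
  for (rn in rownames(rows)) {
    lines <- c(lines, svg_text(bar_x - 10, y + bar_h - 8, rn, size = 13,
                               anchor = "end"))
    x <- bar_x
    for (lev in c("low", "unclear", "high")) {
      w <- bar_w * rows[rn, lev] / 100
      if (w > 0) {
        lines <- c(lines, svg_rect(x, y, w, bar_h, spec$color_map[[lev]]))
        if (w > 34) {
          lines <- c(lines, svg_text(x + w / 2, y + bar_h - 8,
                                     sprintf("%.1f%%", rows[rn, lev]),
                                     size = 11, anchor = "middle"))
        }
        x <- x + w
      }
    }
    y <- y + gap
  }
  lines <- c(lines, svg_legend(bar_x, y + 8, spec$color_map))
  if (identical(spec$output_format, "png")) {
    return(render_png_fallback(path, function()
      plot(summary)))
  }
  write_svg(lines, path)
}

#' Render the per-study traffic-light matrix
#'
#' A matrix of coloured cells, one row per study (sorted by id) and one
#' column per domain plus the overall rating, following the traffic-light
#' convention of risk-of-bias summaries. Layout is deterministic.
#'
#' @param assessments an `ndd_assessment_set`.
#' @param path output file path.
#' @param spec a [figure_spec()].
#' @return `path`, invisibly.
#' @export
render_traffic_light <- function(assessments, path,
                                 spec = figure_spec("traffic_light")) {
  stopifnot(inherits(assessments, "ndd_assessment_set"),
            length(assessments) >= 1L)
  ids <- vapply(assessments, `[[`, character(1), "study_id")
  ord <- order(ids)
  cell <- 26; label_w <- 150; top <- 40
  cols <- c(paste0("D", 1:4), "Overall")
  width <- as.integer(label_w + cell * 5 + 200)
  height <- as.integer(top + cell * length(assessments) + 50)
  lines <- svg_open(width, height)
  for (j in seq_along(cols)) {
    lines <- c(lines, svg_text(label_w + (j - 0.5) * cell, top - 8,
                               cols[j], size = 11, anchor = "middle"))
  }
  y <- top
  for (i in ord) {
    a <- assessments[[i]]
    lines <- c(lines, svg_text(label_w - 8, y + cell - 9, a$study_id,
                               size = 11, anchor = "end"))
    vals <- ratings(a)
    for (j in seq_along(vals)) {
      lines <- c(lines, svg_rect(label_w + (j - 1) * cell, y, cell, cell,
                                 spec$color_map[[vals[j]]]))
    }
    y <- y + cell
  }
  lines <- c(lines, svg_legend(label_w, y + 24, spec$color_map))
  if (identical(spec$output_format, "png")) {
    return(render_png_fallback(path, function()
      plot_traffic_base(assessments, spec)))
  }
  write_svg(lines, path)
}

# PNG via the standard device; not byte-deterministic, provided for
# convenience only
render_png_fallback <- function(path, draw) {
  grDevices::png(path, width = 800, height = 500)
  on.exit(grDevices::dev.off())
  draw()
  invisible(path)
}

plot_traffic_base <- function(assessments, spec) {
  ids <- sort(vapply(assessments, `[[`, character(1), "study_id"))
  m <- t(vapply(assessments[order(vapply(assessments, `[[`, character(1),
                                         "study_id"))],
                ratings, character(5)))
  graphics::image(seq_len(5), seq_along(ids),
                  t(matrix(match(m, c("low", "unclear", "high",
                                      "no_information")),
                           nrow = nrow(m)))[, rev(seq_along(ids)),
                                            drop = FALSE],
                  col = unname(spec$color_map), axes = FALSE,
                  xlab = "", ylab = "", zlim = c(1, 4))
  graphics::axis(1, at = 1:5, labels = c(paste0("D", 1:4), "Overall"))
  graphics::axis(2, at = seq_along(ids), labels = rev(ids), las = 2)
}

#' @export
plot.ndd_summary <- function(x, colors = risk_colors(), ...) {
  m <- rbind(x$domain_distribution, Overall = x$overall_distribution)
  rownames(m)[1:4] <- paste0("D", 1:4)
  graphics::barplot(t(m[rev(seq_len(nrow(m))), , drop = FALSE]),
                    horiz = TRUE, las = 1,
                    col = colors[c("low", "unclear", "high")],
                    xlab = "% of studies", ...)
  graphics::legend("topright", legend = c("low", "unclear", "high"),
                   fill = colors[c("low", "unclear", "high")], bty = "n")
  invisible(x)
}

#' @export
plot.ndd_assessment_set <- function(x, spec = figure_spec("traffic_light"),
                                    ...) {
  plot_traffic_base(x, spec)
  invisible(x)
}

#' Render a markdown assessment report
#'
#' A human-readable report: one section per study listing the four domain
#' ratings with their rationale strings and any per-finding overlap risks,
#' followed by the cohort summary table. Generation fails if any rationale
#' string is empty.
#'
#' @param assessments an `ndd_assessment_set`.
#' @param summary the matching `ndd_summary`.
#' @param path output file path (markdown).
#' @return `path`, invisibly.
#' @export
render_report <- function(assessments, summary, path) {
  stopifnot(inherits(assessments, "ndd_assessment_set"),
            inherits(summary, "ndd_summary"))
  out <- c("# Risk-of-bias assessment report", "")
  for (a in assessments[order(vapply(assessments, `[[`, character(1),
                                     "study_id"))]) {
    out <- c(out, sprintf("## %s", a$study_id), "")
    for (d in a$domains) {
      if (!nzchar(d$rationale)) {
        stop(sprintf("empty rationale for domain %d of study '%s'",
                     d$domain_id, a$study_id), call. = FALSE)
      }
      out <- c(out, sprintf("- **Domain %d: %s** — %s", d$domain_id,
                            d$rating, d$rationale))
    }
    out <- c(out, sprintf("- **Overall: %s**", a$overall))
    if (length(a$finding_risks) > 0L) {
      out <- c(out, sprintf("- Finding-level overlap risks: %s",
                            paste(a$finding_risks, collapse = ", ")))
    }
    out <- c(out, "")
  }
  out <- c(out, "## Cohort summary", "",
           sprintf("- Studies: %d", summary$n_studies),
           sprintf("- Participating children: %d", summary$total_children),
           sprintf("- Scale scores: %d", summary$n_scale_scores),
           sprintf("- Distinct instruments: %d",
                   summary$n_distinct_instruments),
           "",
           "| Level | D1 | D2 | D3 | D4 | Overall |",
           "|---|---|---|---|---|---|")
  for (lev in c("low", "unclear", "high")) {
    out <- c(out, sprintf("| %s | %.1f | %.1f | %.1f | %.1f | %.1f |", lev,
                          summary$domain_distribution["d1", lev],
                          summary$domain_distribution["d2", lev],
                          summary$domain_distribution["d3", lev],
                          summary$domain_distribution["d4", lev],
                          summary$overall_distribution[[lev]]))
  }
  pcts <- c(
    "Studies with >= 1 overlap" = summary$pct_studies_with_overlap,
    "Overlap studies with unaddressed overlap" =
      summary$pct_overlap_studies_unaddressed,
    "Counted scores carrying overlap" = summary$pct_outcomes_with_overlap,
    "Multi-informant studies" = summary$pct_multi_informant,
    "Single informant justified by young age" =
      summary$pct_single_informant_justified,
    "Child perspective missing" = summary$pct_child_missing,
    "Self-report feasible among missing" =
      summary$pct_feasible_among_missing,
    "Instruments designed for NDD" =
      summary$pct_instruments_designed_for_ndd)
  out <- c(out, "")
  for (nm in names(pcts)) {
    out <- c(out, sprintf("- %s: %.1f%%", nm, pcts[[nm]]))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(out, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
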