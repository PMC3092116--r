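#' Fuse per-stage results into one row per gene
#'
#' Outer join of stage outputs keyed by gene id. Gene ids are canonicalized
#' to upper case; a case conflict is resolved and reported via a message.
#' Duplicate gene ids within one stage are an error naming the offenders.
#' Per-field provenance (which stage supplied which column) is recorded in
#' the `"provenance"` attribute. Missing fields stay `NA` and are rendered
#' blank, never as 0.
#'
#' @param stages Named list of `data.frame`s, each with a `gene` column plus
#'   result fields (e.g. `fc`, `survival_p`, `gain_freq`, ...). Column names
#'   other than `gene` must be unique across stages.
#' @return `data.frame` with one row per gene; attribute `"provenance"` maps
#'   each field to its stage.
#' @export
build_gene_table <- function(stages) {
  stopifnot(is.list(stages), !is.null(names(stages)))
  provenance <- character(0)
  canon <- new.env(parent = emptyenv())
  tabs <- lapply(names(stages), function(nm) {
    df <- stages[[nm]]
    if (!"gene" %in% names(df))
      stop("stage '", nm, "' has no 'gene' column", call. = FALSE)
    up <- toupper(df$gene)
    changed <- up != df$gene
    if (any(changed))
      message("stage '", nm, "': canonicalized gene name case for ",
              sum(changed), " gene(s)")
    df$gene <- up
    dup <- unique(df$gene[duplicated(df$gene)])
    if (length(dup))
      stop("stage '", nm, "' has duplicate gene ids: ",
           paste(dup, collapse = ", "), call. = FALSE)
    provenance <<- c(provenance,
                     setNames(rep(nm, ncol(df) - 1L),
                              setdiff(names(df), "gene")))
    df
  })
  out <- Reduce(function(a, b) merge(a, b, by = "gene", all = TRUE), tabs)
  attr(out, "provenance") <- provenance
  out
}

# Internal: red/green fold-change cell color on a log2 ramp saturating at
# |log2 FC| = 3. Red = upregulation (FC > 1), green = downregulation.
fc_color <- function(fc) {
  vapply(fc, function(f) {
    if (is.na(f) || f <= 0) return("#ffffff")
    s <- min(abs(log2(f)) / 3, 1)
    other <- sprintf("%02x", round(255 * (1 - s)))
    if (f > 1) paste0("#ff", other, other) else paste0("#", other, "ff", other)
  }, "")
}

# Internal: P-value cell color: red intensity increasing as P decreases.
p_color <- function(p, gate = 0.01) {
  vapply(p, function(x) {
    if (is.na(x) || x >= 0.05) return("#ffffff")
    s <- min(-log10(x) / 6, 1)
    other <- sprintf("%02x", round(255 * (1 - 0.7 * s)))
    paste0("#ff", other, other)
  }, "")
}

fmt_cell <- function(x, digits = 3) {
  ifelse(is.na(x), "",
         ifelse(abs(x) < 0.001 & x != 0, sprintf("%.2e", x),
                trimws(formatC(x, digits = digits, format = "fg"))))
}

#' Kaplan-Meier curves as a self-contained SVG plot
#'
#' Hand-rendered SVG step curves (one per expression group) with dotted 95%
#' confidence bands, so the report site needs no graphics device and stays
#' plain text.
#'
#' @param groups Named list of `data.frame`s from [kaplan_meier()], one per
#'   group (names are the group labels, e.g. `"1"`, `"0"`, `"-1"`).
#' @param path Output `.svg` path.
#' @param title Plot title.
#' @param width,height Pixel dimensions.
#' @return `path`, invisibly.
#' @export
km_plot_svg <- function(groups, path, title = "Kaplan-Meier",
                        width = 480, height = 360) {
  pal <- c("#d62728", "#1f77b4", "#2ca02c", "#9467bd", "#8c564b")
  mx <- max(vapply(groups, function(g) max(g$time), 0))
  if (mx <= 0) mx <- 1
  margin <- 45
  px <- function(t) margin + (t / mx) * (width - margin - 15)
  py <- function(s) (height - margin) - s * (height - margin - 25)
  step_path <- function(t, s) {
    t <- c(0, t); s <- c(1, s)
    d <- sprintf("M %.1f %.1f", px(t[1]), py(s[1]))
    for (i in 2:length(t))
      d <- paste(d, sprintf("L %.1f %.1f L %.1f %.1f",
                            px(t[i]), py(s[i - 1]), px(t[i]), py(s[i])))
    d
  }
  lines <- c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">',
                     width, height),
             sprintf('<text x="%d" y="16" font-size="13" font-family="sans-serif">%s</text>',
                     margin, title),
             sprintf('<line x1="%d" y1="%.1f" x2="%.1f" y2="%.1f" stroke="black"/>',
                     margin, py(0), px(mx), py(0)),
             sprintf('<line x1="%d" y1="%.1f" x2="%d" y2="%.1f" stroke="black"/>',
                     margin, py(0), margin, py(1)),
             sprintf('<text x="%.1f" y="%.1f" font-size="11" font-family="sans-serif">months</text>',
                     px(mx / 2), py(0) + 30),
             sprintf('<text x="8" y="%.1f" font-size="11" font-family="sans-serif">S(t)</text>',
                     py(0.5)))
  for (tick in pretty(c(0, mx))) {
    if (tick < 0 || tick > mx) next
    lines <- c(lines,
               sprintf('<line x1="%.1f" y1="%.1f" x2="%.1f" y2="%.1f" stroke="black"/>',
                       px(tick), py(0), px(tick), py(0) + 4),
               sprintf('<text x="%.1f" y="%.1f" font-size="10" font-family="sans-serif" text-anchor="middle">%s</text>',
                       px(tick), py(0) + 16, tick))
  }
  for (tick in c(0, 0.5, 1)) {
    lines <- c(lines,
               sprintf('<line x1="%.1f" y1="%.1f" x2="%d" y2="%.1f" stroke="black"/>',
                       margin - 4, py(tick), margin, py(tick)),
               sprintf('<text x="%.1f" y="%.1f" font-size="10" font-family="sans-serif" text-anchor="end">%s</text>',
                       margin - 7, py(tick) + 3, tick))
  }
  for (i in seq_along(groups)) {
    g <- groups[[i]]
    col <- pal[((i - 1) %% length(pal)) + 1]
    lines <- c(lines,
               sprintf('<path d="%s" fill="none" stroke="%s" stroke-width="2"/>',
                       step_path(g$time, g$surv), col))
    ok <- !is.na(g$lower) & !is.na(g$upper)
    if (any(ok)) {
      lines <- c(lines,
        sprintf('<path d="%s" fill="none" stroke="%s" stroke-width="1" stroke-dasharray="3,3"/>',
                step_path(g$time[ok], pmax(g$lower[ok], 0)), col),
        sprintf('<path d="%s" fill="none" stroke="%s" stroke-width="1" stroke-dasharray="3,3"/>',
                step_path(g$time[ok], pmin(g$upper[ok], 1)), col))
    }
    lines <- c(lines,
               sprintf('<text x="%.1f" y="%d" font-size="11" font-family="sans-serif" fill="%s">group %s</text>',
                       width - 110, 20 + 14 * i, col, names(groups)[i]))
  }
  writeLines(c(lines, "</svg>"), path)
  invisible(path)
}

# Default external link templates; rendered as plain URL hrefs, never fetched.
default_link_templates <- function() {
  c(GeneCards = "https://www.genecards.org/cgi-bin/carddisp.pl?gene=%s",
    Ensembl = "https://www.ensembl.org/Homo_sapiens/Gene/Summary?g=%s",
    KEGG = "https://www.genome.jp/dbget-bin/www_bget?hsa:%s",
    PINA = "https://omics.bjcancer.org/pina/interactome.stat.do?gene=%s")
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Render the browsable static result website
#'
#' Writes a self-contained static site: an index page with one row per gene,
#' column-sortable via a small inline script, fold-change cells colored red
#' (upregulation) / green (downregulation) on a log2 ramp saturating at
#' |log2 FC| = 3, P-value cells shaded red by significance, per-gene
#' subpages with per-transcript rows and external database links rendered
#' from URL templates. A Kaplan-Meier SVG is embedded on a gene page only
#' when that feature's survival P < 0.01. Numbers are taken verbatim from
#' the fused table; nothing is recomputed at render time, and missing values
#' render blank.
#'
#' @param rows Fused gene table from [build_gene_table()].
#' @param out_dir Output directory (created if needed).
#' @param sort_key Column used for the initial row order (default
#'   `"survival_p"`, ascending).
#' @param transcripts Optional `data.frame` with per-transcript rows
#'   (`gene`, `transcript`, `fc`, `survival_p`).
#' @param km_groups Optional named list (by feature id: gene or transcript)
#'   of group lists for [km_plot_svg()].
#' @param km_gate Survival-P gate for embedding KM plots (default 0.01).
#' @param link_templates Named character vector of `sprintf` URL templates.
#' @return `out_dir`, invisibly.
#' @export
render_website <- function(rows, out_dir, sort_key = "survival_p",
                           transcripts = NULL, km_groups = NULL,
                           km_gate = 0.01,
                           link_templates = default_link_templates()) {
  if (nrow(rows) == 0L) stop("no rows to render", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output dir: ", out_dir,
                                 call. = FALSE)
  if (sort_key %in% names(rows))
    rows <- rows[order(rows[[sort_key]], na.last = TRUE), , drop = FALSE]
  num_cols <- setdiff(names(rows), "gene")
  css <- paste(
    "table{border-collapse:collapse;font-family:sans-serif;font-size:13px}",
    "th,td{border:1px solid #bbb;padding:3px 7px;text-align:right}",
    "th{cursor:pointer;background:#eee}", "td.g{text-align:left}", sep = "\n")
  js <- paste0(
    "function sortTable(c){var t=document.getElementById('genes');",
    "var r=Array.from(t.tBodies[0].rows);var d=t.dataset.dir!=='asc';",
    "r.sort(function(a,b){var x=a.cells[c].textContent,y=b.cells[c].textContent;",
    "var nx=parseFloat(x),ny=parseFloat(y);",
    "if(!isNaN(nx)&&!isNaN(ny))return d?nx-ny:ny-nx;",
    "if(x==='')return 1;if(y==='')return -1;",
    "return d?x.localeCompare(y):y.localeCompare(x);});",
    "t.dataset.dir=d?'asc':'desc';",
    "r.forEach(function(w){t.tBodies[0].appendChild(w);});}")
  header <- c("<!DOCTYPE html><html><head><meta charset='utf-8'>",
              "<title>Gene report</title>",
              paste0("<style>", css, "</style>"),
              paste0("<script>", js, "</script>"), "</head><body>")
  th <- c("<th onclick='sortTable(0)'>gene</th>",
          sprintf("<th onclick='sortTable(%d)'>%s</th>",
                  seq_along(num_cols), html_escape(num_cols)))
  body_rows <- vapply(seq_len(nrow(rows)), function(i) {
    g <- rows$gene[i]
    tds <- vapply(num_cols, function(cn) {
      v <- rows[[cn]][i]
      col <- if (grepl("fc|min|max|gain|loss|beta", cn)) fc_color(v)
             else if (grepl("_p$|^p_", cn)) p_color(v)
             else "#ffffff"
      sprintf("<td style='background:%s'>%s</td>", col, fmt_cell(v))
    }, "")
    sprintf("<tr><td class='g'><a href='gene_%s.html'>%s</a></td>%s</tr>",
            g, html_escape(g), paste(tds, collapse = ""))
  }, "")
  writeLines(c(header, "<h2>Gene-level integrated results</h2>",
               "<table id='genes'><thead><tr>", th, "</tr></thead><tbody>",
               body_rows, "</tbody></table></body></html>"),
             file.path(out_dir, "index.html"))
  for (i in seq_len(nrow(rows))) {
    g <- rows$gene[i]
    links <- sprintf("<li><a href='%s'>%s</a></li>",
                     vapply(link_templates, sprintf, "", g),
                     html_escape(names(link_templates)))
    fields <- sprintf("<tr><td class='g'>%s</td><td>%s</td></tr>",
                      html_escape(num_cols),
                      vapply(num_cols, function(cn) fmt_cell(rows[[cn]][i]), ""))
    tx_block <- ""
    if (!is.null(transcripts)) {
      tx <- transcripts[toupper(transcripts$gene) == g, , drop = FALSE]
      if (nrow(tx)) {
        tx_rows <- vapply(seq_len(nrow(tx)), function(k) {
          p <- tx$survival_p[k]
          km_tag <- ""
          id <- tx$transcript[k]
          if (!is.na(p) && p < km_gate && !is.null(km_groups) &&
              id %in% names(km_groups)) {
            svg <- sprintf("km_%s.svg", id)
            km_plot_svg(km_groups[[id]], file.path(out_dir, svg),
                        title = sprintf("%s (log-rank P = %s)", id,
                                        fmt_cell(p)))
            km_tag <- sprintf("<br/><img src='%s' alt='KM %s'/>", svg, id)
          }
          sprintf("<tr><td class='g'>%s</td><td>%s</td><td>%s%s</td></tr>",
                  html_escape(id), fmt_cell(tx$fc[k]),
                  fmt_cell(p), km_tag)
        }, "")
        tx_block <- paste0("<h3>Transcripts</h3><table><tr><th>transcript</th>",
                           "<th>FC</th><th>survival P</th></tr>",
                           paste(tx_rows, collapse = ""), "</table>")
      }
    }
    writeLines(c("<!DOCTYPE html><html><head><meta charset='utf-8'>",
                 sprintf("<title>%s</title>", html_escape(g)),
                 paste0("<style>", css, "</style></head><body>"),
                 sprintf("<h2>%s</h2>", html_escape(g)),
                 "<p><a href='index.html'>back to index</a></p>",
                 "<table><tr><th>field</th><th>value</th></tr>", fields,
                 "</table>", tx_block,
                 "<h3>External links</h3><ul>", links, "</ul>",
                 "</body></html>"),
               file.path(out_dir, sprintf("gene_%s.html", g)))
  }
  invisible(out_dir)
}

#' Write the fused gene table as TSV and JSON
#'
#' @param rows Fused gene table.
#' @param out_dir Output directory.
#' @return Paths of the two files, invisibly.
#' @export
write_gene_table <- function(rows, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(out_dir, "gene_table.tsv")
  js <- file.path(out_dir, "gene_table.json")
  write_tsv_table(rows, tsv)
  jsonlite::write_json(rows, js, dataframe = "rows", na = "null",
                       auto_unbox = TRUE, digits = NA)
  invisible(c(tsv = tsv, json = js))
}
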