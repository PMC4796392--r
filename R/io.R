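# Readers, report objects and layout rendering shared by the command-line
# subcommands.

# delimiter sniffing: tab wins if present in the header, else comma
.read_table_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) stop("empty file: ", path)
  sep <- if (grepl("\t", header)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Read a compound score table into score sets
#'
#' CSV/TSV with a header; one row per compound, a binary label column
#' (1 = active, 0 = inactive) and one numeric score column per method. Rows
#' stay aligned across methods, as the correlated-difference statistics
#' require.
#'
#' @param path File path.
#' @param label_col Name of the label column, default `"label"`.
#' @param method_cols Character vector of score columns; default all other
#'   numeric columns.
#' @return Named list of [score_set()] objects, one per method column.
#' @export
read_score_table <- function(path, label_col = "label", method_cols = NULL) {
  df <- .read_table_auto(path)
  if (!label_col %in% names(df))
    stop("label column '", label_col, "' not found")
  lab <- df[[label_col]]
  if (!all(lab %in% c(0, 1)))
    stop("labels must be coded 0 (inactive) / 1 (active)")
  if (is.null(method_cols)) {
    method_cols <- setdiff(names(df), label_col)
    method_cols <- method_cols[vapply(df[method_cols], is.numeric, logical(1))]
  }
  if (length(method_cols) == 0) stop("no numeric score columns found")
  missing <- setdiff(method_cols, names(df))
  if (length(missing))
    stop("score column(s) not found: ", paste(missing, collapse = ", "))
  lapply(stats::setNames(method_cols, method_cols), function(mc) {
    s <- df[[mc]]
    if (!is.numeric(s)) stop("non-numeric scores in column '", mc, "'")
    if (anyNA(s)) stop("missing scores in column '", mc, "'")
    score_set(s[lab == 1], s[lab == 0], mc)
  })
}

#' Read a performance matrix file
#'
#' CSV/TSV with a header: first column system labels, remaining columns one
#' numeric column per method.
#'
#' @param path File path.
#' @param transpose Set `TRUE` if the file is oriented methods-in-rows.
#' @return A [performance_matrix()].
#' @export
read_performance_matrix <- function(path, transpose = FALSE) {
  df <- .read_table_auto(path)
  if (ncol(df) < 2) stop("need a label column plus at least one method")
  labels <- as.character(df[[1]])
  if (anyDuplicated(labels)) stop("duplicate system labels")
  m <- as.matrix(df[-1])
  if (!is.numeric(m)) stop("non-numeric cells in performance matrix")
  rownames(m) <- labels
  if (transpose) m <- t(m)
  performance_matrix(m)
}

#' Render an equivalence-grouping layout
#'
#' Text mode prints one column of methods per display column (best column
#' left), each method with its mean, plus the list of dotted cross-column
#' equivalence edges. SVG mode draws the canonical circles-in-columns
#' depiction with dotted lines between cross-column equivalent methods.
#' Output is deterministic for a fixed layout.
#'
#' @param gl A [grouping_layout()].
#' @param format `"text"` or `"svg"`.
#' @return A single character string (the document).
#' @export
render_layout <- function(gl, format = c("text", "svg")) {
  format <- match.arg(format)
  stopifnot(inherits(gl, "grouping_layout"))
  if (format == "text") .render_layout_text(gl) else .render_layout_svg(gl)
}

.render_layout_text <- function(gl) {
  cols <- gl$columns
  depth <- max(lengths(cols))
  cell <- function(lab) sprintf("%s (%.3g)", lab, gl$means[[lab]])
  width <- max(nchar(vapply(unlist(cols), cell, character(1)))) + 2
  lines <- vapply(seq_len(depth), function(row) {
    paste0(vapply(cols, function(cl) {
      txt <- if (row <= length(cl)) cell(cl[row]) else ""
      formatC(txt, width = width, flag = "-")
    }, character(1)), collapse = "")
  }, character(1))
  out <- paste0(paste(trimws(lines, "right"), collapse = "\n"), "\n")
  if (!is.null(gl$edges)) {
    out <- paste0(out, "equivalent across columns: ",
                  paste(apply(gl$edges, 1, paste, collapse = " - "),
                        collapse = ", "), "\n")
  }
  out
}

.render_layout_svg <- function(gl) {
  cols <- gl$columns
  r <- 28; dx <- 90; dy <- 80; pad <- 50
  width <- pad * 2 + dx * (length(cols) - 1)
  height <- pad * 2 + dy * (max(lengths(cols)) - 1)
  pos <- list()
  for (ci in seq_along(cols)) {
    for (ri in seq_along(cols[[ci]])) {
      pos[[cols[[ci]][ri]]] <- c(pad + dx * (ci - 1), pad + dy * (ri - 1))
    }
  }
  el <- character(0)
  if (!is.null(gl$edges)) {
    el <- apply(gl$edges, 1, function(e) {
      p1 <- pos[[e[1]]]; p2 <- pos[[e[2]]]
      sprintf(paste0('<line x1="%d" y1="%d" x2="%d" y2="%d" stroke="black" ',
                     'stroke-dasharray="4 4"/>'),
              p1[1], p1[2], p2[1], p2[2])
    })
  }
  circles <- vapply(names(pos), function(lab) {
    p <- pos[[lab]]
    paste0(
      sprintf('<circle cx="%d" cy="%d" r="%d" fill="white" stroke="black"/>',
              p[1], p[2], r),
      sprintf('<text x="%d" y="%d" text-anchor="middle" font-size="11">%s</text>',
              p[1], p[2] - 4, lab),
      sprintf('<text x="%d" y="%d" text-anchor="middle" font-size="10">%.3g</text>',
              p[1], p[2] + 10, gl$means[[lab]])
    )
  }, character(1))
  paste0('<svg xmlns="http://www.w3.org/2000/svg" width="', width,
         '" height="', height, '">\n',
         paste(el, collapse = "\n"), if (length(el)) "\n" else "",
         paste(circles, collapse = "\n"),
         "\n</svg>\n")
}

#' Assemble a machine-readable comparison report
#'
#' A uniform envelope for every comparison the package performs: the
#' operation name, input digest, estimates, intervals, statistics, verdicts,
#' warnings and the seed in play. Serialises losslessly to JSON; the schema
#' ships at `system.file("schema", "comparison-report.json",
#' package = "mmcompare")`.
#'
#' @param operation Operation name (e.g. `"pair"`, `"roc"`).
#' @param estimates Named list/vector of point estimates.
#' @param intervals Named list of [asym_interval()]s (or NULL).
#' @param statistics Named list of test statistics and critical values.
#' @param verdicts Named list/vector of verdict strings.
#' @param warnings Character vector of surfaced warnings.
#' @param inputs Named list describing the inputs (paths, n, parameters).
#' @param seed Seed used, if any.
#' @return Object of class `comparison_report`.
#' @export
comparison_report <- function(operation, estimates = list(),
                              intervals = NULL, statistics = list(),
                              verdicts = list(), warnings = character(0),
                              inputs = list(), seed = NULL) {
  iv <- NULL
  if (!is.null(intervals)) {
    iv <- lapply(intervals, function(x) {
      if (inherits(x, "asym_interval"))
        list(estimate = x$estimate, lower = x$estimate - x$lower,
             upper = x$estimate + x$upper, level = x$level)
      else x
    })
  }
  structure(list(tool = "mmcompare",
                 version = as.character(utils::packageVersion("mmcompare")),
                 operation = operation, inputs = inputs,
                 estimates = estimates, intervals = iv,
                 statistics = statistics, verdicts = verdicts,
                 warnings = warnings, seed = seed),
            class = "comparison_report")
}

#' Serialise a comparison report to JSON
#'
#' @param report A [comparison_report()].
#' @param path Optional output path; when `NULL` the JSON string is returned.
#' @param digits Significant digits for floats, default 6.
#' @return The JSON string, invisibly when written to a file.
#' @export
write_report <- function(report, path = NULL, digits = 6) {
  stopifnot(inherits(report, "comparison_report"))
  json <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = digits,
                           null = "null", pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
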