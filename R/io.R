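# Graph readers (SIF, TSV edge table) and the tab-delimited results dialect.

#' Read a SIF interaction file
#'
#' Simple interaction format: one record per line,
#' `source <delim> etype <delim> target [target2 ...]`, tab-delimited, or
#' space-delimited when a line contains no tab. Lines with several targets
#' expand to one edge per target. SIF carries no weights, so graphs built
#' from it use default-weight mode.
#'
#' @param path File path.
#' @return A raw-edge tibble (`source`, `target`, `etype`, `weight = NA`).
#' @export
read_sif <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  rows <- purrr::map(lines, function(ln) {
    fields <- if (grepl("\t", ln, fixed = TRUE)) {
      strsplit(ln, "\t", fixed = TRUE)[[1]]
    } else {
      strsplit(ln, "[[:space:]]+")[[1]]
    }
    fields <- fields[nzchar(fields)]
    if (length(fields) < 3) {
      abort_validation(paste0("SIF line with fewer than 3 fields: '", ln, "'"))
    }
    tibble(source = fields[1], target = fields[-(1:2)], etype = fields[2])
  })
  out <- dplyr::bind_rows(rows)
  out$weight <- NA_real_
  out
}

#' Read a TSV edge table
#'
#' Tab-delimited, UTF-8, `#` comment lines skipped. Requires columns
#' `source`, `target` and `etype`; a `weight` column is optional and its
#' presence switches graph construction to attribute-weight mode (see
#' [flow_graph()]).
#'
#' @param path File path.
#' @return A raw-edge tibble.
#' @export
read_edge_table <- function(path) {
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  missing <- setdiff(c("source", "target", "etype"), names(tab))
  if (length(missing) > 0) {
    abort_validation(paste0(
      "Edge table is missing column(s): ", paste(missing, collapse = ", ")
    ))
  }
  validate_raw_edges(tab)
}

model_code <- function(model) {
  switch(model, emitting = "E", absorbing = "A", channel = "C")
}

#' Render a result-attribute label
#'
#' Attribute columns in exported results are labelled
#' `ITM<model code><run id>[<boundary tag>]`, e.g. `ITME243[S1]` for the
#' visits from source `S1` in emitting run 243. Users can add custom columns
#' under their own tags (e.g. an average of two sources) and rank or color
#' by them after re-import.
#'
#' @param model `"emitting"`, `"absorbing"` or `"channel"`.
#' @param run_id Positive integer, cosmetic run identifier.
#' @param tag Boundary node id or derived tag.
#' @return The rendered label string.
#' @examples
#' itm_label("emitting", 243, "S1") # "ITME243[S1]"
#' @export
itm_label <- function(model, run_id, tag) {
  sprintf("ITM%s%d[%s]", model_code(model), as.integer(run_id), tag)
}

#' Next run id for an output directory
#'
#' Maintains a monotonically increasing counter in a sidecar file
#' `.itm-run-id` next to the results; purely cosmetic labelling.
#'
#' @param dir Output directory.
#' @return Integer run id.
#' @export
next_run_id <- function(dir) {
  sidecar <- file.path(dir, ".itm-run-id")
  last <- if (file.exists(sidecar)) {
    suppressWarnings(as.integer(readLines(sidecar, n = 1)[1]))
  } else {
    NA_integer_
  }
  nxt <- if (is.na(last)) 1L else last + 1L
  writeLines(as.character(nxt), sidecar)
  nxt
}

# full-precision decimal rendering that survives a text round trip exactly
num_repr <- function(x) sprintf("%.17g", x)

result_value_matrix <- function(result) {
  switch(result$model,
    emitting = t(result$H),
    absorbing = result$F,
    channel = t(result$Phi_hat)
  )
}

#' Export a flow result as a tab-delimited file
#'
#' The file is self-contained up to the query network: `#`-prefixed
#' `key<TAB>value` header lines record the model, damping factor, criterion,
#' boundary and excluded nodes and the summary statistic, followed by a
#' column header (`node_id`, one [itm_label()] column per boundary node,
#' `total`, `interference` for emitting/channel, `color`) and one row per
#' node with any nonzero value, in full decimal precision, ordered by
#' descending total (ties by node id). Re-import with [read_itm_tsv()].
#'
#' @param result An `itm_flow`.
#' @param path Output file path.
#' @param selection Optional [select_nodes()] result; recorded in the header.
#' @param run_id Positive integer label; `NULL` draws from the sidecar
#'   counter of the output directory (see [next_run_id()]).
#' @param scaling Scaling function for the exported display colors.
#' @return `path`, invisibly.
#' @export
write_itm_tsv <- function(result, path, selection = NULL, run_id = 1L,
                          scaling = "sqrt") {
  stopifnot(inherits(result, "itm_flow"))
  if (is.null(run_id)) run_id <- next_run_id(dirname(path))
  V <- result_value_matrix(result)
  keep <- rowSums(V != 0) > 0
  V <- V[keep, , drop = FALSE]
  total <- rowSums(V)
  ord <- order(-total, rownames(V), method = "radix")
  V <- V[ord, , drop = FALSE]
  total <- total[ord]

  headers <- c(
    model = result$model,
    mu = num_repr(result$mu),
    criterion_kind = result$criterion$kind %||% "direct_mu",
    criterion_value = num_repr(result$criterion$value %||% result$mu),
    sources = paste(result$sources, collapse = ","),
    sinks = paste(result$sinks, collapse = ","),
    excluded = paste(result$excluded, collapse = ","),
    run_id = as.character(run_id)
  )
  if (!is.null(result$t_bar)) headers["t_bar"] <- num_repr(result$t_bar)
  if (!is.null(result$r_bar)) headers["r_bar"] <- num_repr(result$r_bar)
  if (!is.null(selection)) {
    crit <- attr(selection, "criterion")
    headers["selection"] <- paste0(
      crit$method,
      if (!is.null(crit$k)) paste0(":", crit$k),
      if (!is.null(crit$cutoff)) paste0(":", num_repr(crit$cutoff))
    )
  }

  labels <- vapply(colnames(V), function(tag) {
    itm_label(result$model, run_id, tag)
  }, character(1))
  cols <- c("node_id", labels, "total")
  body <- cbind(rownames(V), matrix(num_repr(V), nrow = nrow(V)),
                num_repr(total))
  if (result$model %in% c("emitting", "channel")) {
    cols <- c(cols, "interference")
    body <- cbind(body, num_repr(apply(V, 1, min)))
  }
  cols <- c(cols, "color")
  hex <- if (nrow(V) > 0) {
    color_cols <- as.data.frame(V[, seq_len(min(3, ncol(V))), drop = FALSE])
    mix_colors(cbind(tibble(node = rownames(V)), color_cols),
               scaling = scaling)$color
  } else {
    character()
  }
  body <- cbind(body, hex)

  rows <- if (nrow(body) > 0) {
    apply(body, 1, paste, collapse = "\t")
  } else {
    character()
  }
  lines <- c(
    paste0("#", names(headers), "\t", unname(headers)),
    paste(cols, collapse = "\t"),
    rows
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Import a tab-delimited flow result
#'
#' Reads a file written by [write_itm_tsv()] back into a flow result and a
#' ranked selection. Rows whose node id does not occur in `graph` are skipped
#' (with a message reporting the count), mirroring import into a network
#' other than the original query network. Columns that are not part of the
#' dialect are preserved as custom ranking attributes.
#'
#' @param path File path.
#' @param graph The `itm_graph` to match node ids against.
#' @return A list with elements `result` (an `itm_flow`; for channel imports
#'   only `Phi_hat` is recoverable), `selection`, `skipped` (row count) and
#'   `run_id`.
#' @export
read_itm_tsv <- function(path, graph) {
  stopifnot(inherits(graph, "itm_graph"))
  lines <- readLines(path, encoding = "UTF-8")
  is_header <- startsWith(lines, "#")
  n_head <- match(FALSE, is_header) - 1L
  if (is.na(n_head) || n_head < 1 || length(lines) < n_head + 1) {
    abort_validation("Malformed results file: missing '#' header block (line 1).")
  }
  hlines <- sub("^#", "", lines[seq_len(n_head)])
  bad <- which(!grepl("\t", hlines, fixed = TRUE))
  if (length(bad) > 0) {
    abort_validation(sprintf("Malformed header at line %d.", bad[1]))
  }
  hdr <- setNames(sub("^[^\t]*\t", "", hlines), sub("\t.*$", "", hlines))
  model <- hdr[["model"]]
  if (!model %in% c("emitting", "absorbing", "channel")) {
    abort_validation(sprintf("Malformed header: unknown model '%s' (line %d).",
                             model, match("model", names(hdr))))
  }

  cols <- strsplit(lines[n_head + 1L], "\t", fixed = TRUE)[[1]]
  if (cols[1] != "node_id") {
    abort_validation(sprintf("Malformed column header at line %d.", n_head + 1L))
  }
  data_lines <- lines[-seq_len(n_head + 1L)]
  data_lines <- data_lines[nzchar(data_lines)]
  cells <- strsplit(data_lines, "\t", fixed = TRUE)
  wrong <- which(lengths(cells) != length(cols))
  if (length(wrong) > 0) {
    abort_validation(sprintf("Malformed row at line %d.",
                             n_head + 1L + wrong[1]))
  }
  tab <- as_tibble(setNames(
    purrr::map(seq_along(cols), function(j) {
      vapply(cells, `[`, character(1), j)
    }),
    cols
  ))

  present <- tab$node_id %in% graph$nodes
  skipped <- sum(!present)
  if (skipped > 0) {
    inform(sprintf("Skipped %d row(s) with node ids absent from the graph.",
                   skipped))
  }
  tab <- tab[present, , drop = FALSE]

  attr_cols <- grep("^ITM[EAC][0-9]+\\[.+\\]$", cols, value = TRUE)
  tags <- sub("^ITM[EAC][0-9]+\\[(.+)\\]$", "\\1", attr_cols)
  V <- matrix(0, nrow(tab), length(attr_cols),
              dimnames = list(tab$node_id, tags))
  for (j in seq_along(attr_cols)) V[, j] <- as.numeric(tab[[attr_cols[j]]])

  split_ids <- function(key) {
    v <- hdr[[key]] %||% ""
    if (nzchar(v)) strsplit(v, ",", fixed = TRUE)[[1]] else character()
  }
  mu <- as.numeric(hdr[["mu"]])
  result <- new_itm_flow(
    model = model, mu = mu,
    sources = split_ids("sources"), sinks = split_ids("sinks"),
    excluded = split_ids("excluded"), graph = graph,
    H = if (model == "emitting") t(V),
    F = if (model == "absorbing") V,
    Phi_hat = if (model == "channel") t(V),
    t_bar = if ("t_bar" %in% names(hdr)) as.numeric(hdr[["t_bar"]]),
    r_bar = if ("r_bar" %in% names(hdr)) as.numeric(hdr[["r_bar"]]),
    criterion = dissipation_criterion(hdr[["criterion_kind"]],
                                      as.numeric(hdr[["criterion_value"]]))
  )
  known <- c("node_id", attr_cols, "total", "interference", "color")
  custom_cols <- setdiff(cols, known)
  result$custom <- setNames(
    purrr::map(custom_cols, function(cc) {
      setNames(as.numeric(tab[[cc]]), tab$node_id)
    }),
    custom_cols
  )

  total <- as.numeric(tab$total)
  selection <- structure(
    tibble(node = tab$node_id, value = total) |>
      dplyr::arrange(dplyr::desc(.data$value), .data$node),
    class = c("itm_selection", class(tibble())),
    criterion = list(method = "imported")
  )
  list(result = result, selection = selection, skipped = skipped,
       run_id = as.integer(hdr[["run_id"]] %||% "1"))
}
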