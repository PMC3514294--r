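# Ranking, significant-node selection and display colors for a flow result.

#' Extract a ranking attribute from a flow result
#'
#' For emitting/channel results the available attributes are the visits from
#' each single source, the sum over all sources (`"total"`), and the
#' per-node minimum over sources (`"interference"`). For absorbing results
#' they are the absorption probability to each single sink and the total over
#' sinks (`"total"`). Custom attributes attached to the result (e.g. from an
#' imported results file) pass through by name.
#'
#' @param result An `itm_flow`.
#' @param choice Attribute name: a boundary node id, `"total"`,
#'   `"interference"`, or a custom attribute name.
#' @return Named nonnegative numeric vector over the result's transient nodes.
#' @export
ranking_values <- function(result, choice = "total") {
  stopifnot(inherits(result, "itm_flow"))
  V <- switch(result$model,
    emitting = result$H,
    channel = result$Phi_hat,
    absorbing = t(result$F)
  )
  per <- rownames(V) # boundary ids: sources, or sinks for absorbing
  valid <- c(per, "total",
             if (result$model != "absorbing") "interference",
             names(result$custom))
  if (!choice %in% valid) {
    abort_validation(paste0(
      "Unknown ranking attribute '", choice, "'; valid choices: ",
      paste(valid, collapse = ", ")
    ))
  }
  if (choice %in% names(result$custom)) return(result$custom[[choice]])
  if (choice == "total") return(colSums(V))
  if (choice == "interference") return(interference(result))
  V[choice, ]
}

#' Participation ratio
#'
#' A scale-independent estimate of the effective number of significant values
#' in a nonnegative vector: `(sum v)^2 / sum v^2`, rounded to the nearest
#' integer. Uniform values count every entry; a single spike counts one.
#' Multiplying all values by a positive constant leaves it unchanged, so it
#' gives a selection size that does not depend on the overall flow magnitude.
#'
#' @param values Nonnegative numeric vector with at least one positive entry.
#' @return Integer count of effectively significant entries.
#' @examples
#' participation_ratio(c(1, 1, 1, 1)) # 4
#' participation_ratio(c(2, 1, 1))    # round(16/6) = 3
#' @export
participation_ratio <- function(values) {
  values <- as.numeric(values)
  if (any(is.na(values)) || any(values < 0)) {
    abort_validation("Participation ratio requires nonnegative values.")
  }
  if (all(values == 0)) {
    abort_validation("Participation ratio is undefined for all-zero values.")
  }
  as.integer(round(sum(values)^2 / sum(values^2)))
}

#' Select significant nodes from a ranking attribute
#'
#' Orders nodes by decreasing attribute value (ties broken by node id) and
#' keeps the significant head according to the criterion: the `k` highest
#' positive values (`method = "top_k"`), all values strictly greater than a
#' cutoff (`"cutoff"`), or the top [participation_ratio()] nodes (`"pr"`,
#' the scale-independent default).
#'
#' @param values Named nonnegative numeric vector (see [ranking_values()]).
#' @param method `"pr"`, `"top_k"` or `"cutoff"`.
#' @param k Number of nodes for `"top_k"` (>= 1).
#' @param cutoff Strict lower threshold for `"cutoff"`.
#' @return An `itm_selection` tibble with columns `node`, `value`, ordered by
#'   decreasing value.
#' @export
select_nodes <- function(values, method = c("pr", "top_k", "cutoff"),
                         k = NULL, cutoff = NULL) {
  method <- rlang::arg_match(method)
  if (is.null(names(values))) {
    abort_validation("`values` must be named by node id.")
  }
  ranked <- tibble(node = names(values), value = as.numeric(values)) |>
    dplyr::arrange(dplyr::desc(.data$value), .data$node)
  out <- switch(method,
    pr = head(dplyr::filter(ranked, .data$value > 0),
              participation_ratio(values)),
    top_k = {
      if (is.null(k) || k < 1) abort_validation("`k` must be an integer >= 1.")
      head(dplyr::filter(ranked, .data$value > 0), k)
    },
    cutoff = {
      if (is.null(cutoff)) abort_validation("`cutoff` must be given.")
      dplyr::filter(ranked, .data$value > cutoff)
    }
  )
  structure(out, class = c("itm_selection", class(out)),
            criterion = list(method = method, k = k, cutoff = cutoff))
}

#' Eight-bin sequential palette for single-attribute coloring
#'
#' Config constant used by [mix_colors()] when a single attribute is shown as
#' a discretized sequential map; replace with any vector of hex colors.
#' @export
itm_palette8 <- c("#F7FBFF", "#DEEBF7", "#C6DBEF", "#9ECAE1",
                  "#6BAED6", "#4292C6", "#2171B5", "#084594")

scale_column <- function(v, scaling) {
  s <- switch(scaling, linear = v, sqrt = sqrt(v), log = log1p(v))
  m <- max(s)
  if (m <= 0) rep(0, length(v)) else s / m
}

#' Mix display colors from up to three flow attributes
#'
#' Each attribute is assigned a basic subtractive primary — cyan, magenta,
#' yellow, in column order — and scaled to `[0, 1]` by
#' `scaling(v) / scaling(max v)`. The node color is the subtractive blend
#' `RGB = (1 - c, 1 - m, 1 - y)`: a node with no flow stays white, a node
#' dominated by one attribute takes that attribute's hue, and equal
#' attributes blend (cyan + magenta = blue). With a single attribute and a
#' `palette`, the scaled value is instead discretized into
#' `length(palette)` bins of a sequential map (default [itm_palette8]).
#'
#' @param values A data frame whose first column is the node id and whose
#'   remaining 1 to 3 numeric columns are nonnegative attributes, or a named
#'   numeric vector (single attribute).
#' @param scaling `"sqrt"` (default; tames the dynamic range of flow values),
#'   `"linear"` or `"log"` (uses `log1p`).
#' @param palette Optional vector of hex colors for single-attribute
#'   discretized coloring.
#' @return A tibble with columns `node`, `r`, `g`, `b` (each in `[0, 1]`) and
#'   `color` (hex string).
#' @export
mix_colors <- function(values, scaling = c("sqrt", "linear", "log"),
                       palette = NULL) {
  scaling <- rlang::arg_match(scaling)
  if (is.numeric(values) && !is.null(names(values))) {
    values <- tibble(node = names(values), value = as.numeric(values))
  }
  if (!is.data.frame(values) || ncol(values) < 2) {
    abort_validation("`values` must be a data frame: node id plus 1-3 attribute columns.")
  }
  node <- as.character(values[[1]])
  cols <- values[-1]
  if (ncol(cols) > 3) {
    abort_validation("At most three coloring attributes are supported.")
  }
  M <- as.matrix(cols)
  if (any(M < 0) || any(is.na(M))) {
    abort_validation("Coloring attributes must be nonnegative.")
  }
  S <- apply(M, 2, scale_column, scaling = scaling)
  S <- matrix(S, nrow = length(node))

  if (ncol(S) == 1 && !is.null(palette)) {
    bin <- pmin(length(palette), 1L + floor(S[, 1] * length(palette)))
    bin[S[, 1] <= 0] <- 1L
    hex <- palette[bin]
    rgbm <- t(grDevices::col2rgb(hex)) / 255
    return(tibble(node = node, r = rgbm[, 1], g = rgbm[, 2], b = rgbm[, 3],
                  color = toupper(hex)))
  }

  cmy <- cbind(S, matrix(0, nrow(S), 3 - ncol(S)))
  r <- 1 - cmy[, 1]
  g <- 1 - cmy[, 2]
  b <- 1 - cmy[, 3]
  tibble(node = node, r = r, g = g, b = b,
         color = grDevices::rgb(r, g, b))
}
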