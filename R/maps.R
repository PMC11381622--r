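# Interpretation layers over the latent lattice. Every layer is first-class
# data (a length-K vector aligned to the row-major node indexing plus
# metadata); rendering to SVG is optional so the library stays testable
# headless. Nodes with no defined value carry NA - never 0, since 0 is a
# valid data value.

new_map_layer <- function(grid, values, kind, scheme) {
  stopifnot(length(values) == grid$K)
  structure(list(side = grid$side, values = as.numeric(values), kind = kind,
                 scheme = scheme, row = grid$row, col = grid$col),
            class = "map_layer")
}

#' @export
print.map_layer <- function(x, ...) {
  cat(sprintf("<map_layer:%s> %dx%d lattice, scheme %s, %d undefined node(s)\n",
              x$kind, x$side, x$side, x$scheme, sum(is.na(x$values))))
  invisible(x)
}

#' Membership map: subjects per micro-cluster
#'
#' `values[l]` counts the subjects whose maximum-responsibility node is `l`;
#' the counts partition the cohort, so they sum to N.
#'
#' @param model a fitted `gtm` model.
#' @param data complete numeric matrix or [cohort_table()].
#' @return A `map_layer` of kind `"membership"`.
#' @export
membership_map <- function(model, data) {
  micro <- assign_micro(model, data)
  counts <- tabulate(micro, nbins = model$grid$K)
  new_map_layer(model$grid, counts, "membership", "grey_red")
}

#' Reference map: one variable's component across all reference vectors
#'
#' Shows how strongly a modelling variable loads on each area of the map
#' (grey = low, red = high). By default values are on the standardized
#' modelling scale; supply the model's scaler (or set `original_scale =
#' TRUE` on a model that carries one) to report original units.
#'
#' @param model a fitted `gtm` model.
#' @param variable variable name or column index.
#' @param original_scale if `TRUE`, invert the standardisation using the
#'   scaler stored in the model.
#' @return A `map_layer` of kind `"reference"`, scheme `"grey_red"`.
#' @export
reference_map <- function(model, variable, original_scale = FALSE) {
  y <- reference_vectors(model)
  j <- if (is.character(variable)) match(variable, colnames(y)) else as.integer(variable)
  if (is.na(j) || j < 1L || j > ncol(y)) {
    stop("unknown variable: ", variable)
  }
  vals <- y[, j]
  if (original_scale) {
    if (is.null(model$scaler)) stop("model carries no standardisation parameters")
    name <- colnames(y)[j]
    row <- match(name, model$scaler$variable)
    if (!is.na(row)) {
      vals <- vals * model$scaler$scale[row] + model$scaler$center[row]
    }
  }
  new_map_layer(model$grid, vals, "reference", "grey_red")
}

#' Investigative map: per-node mean of a variable withheld from modelling
#'
#' Averages an external (post-hoc) per-subject variable over the members of
#' each micro-cluster; nodes with no members, or members that are all
#' missing, are undefined (NA). Rendered grey-teal to signal the variable
#' had no influence on the model.
#'
#' @param model a fitted `gtm` model.
#' @param data complete numeric matrix or [cohort_table()] (the modelling
#'   data used for assignment).
#' @param values per-subject numeric vector, length N; may contain `NA`.
#' @return A `map_layer` of kind `"investigative"`, scheme `"grey_teal"`.
#' @export
investigative_map <- function(model, data, values) {
  micro <- assign_micro(model, data)
  values <- as.numeric(values)
  if (length(values) != length(micro)) {
    stop("values must have one entry per subject")
  }
  if (all(is.na(values))) stop("values are all missing")
  sums <- tapply(values, factor(micro, levels = seq_len(model$grid$K)),
                 function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
  new_map_layer(model$grid, as.numeric(sums), "investigative", "grey_teal")
}

#' Per-subject probability map
#'
#' The full posterior distribution of one subject over the latent nodes
#' (their soft assignment), suitable for overlaying on the membership map;
#' values sum to 1.
#'
#' @param model a fitted `gtm` model.
#' @param subject_row complete numeric vector of length D (one subject's
#'   modelling values, standardized scale).
#' @return A `map_layer` of kind `"probability"`.
#' @export
probability_map <- function(model, subject_row) {
  subject_row <- as.numeric(subject_row)
  if (anyNA(subject_row)) stop("subject row contains missing values")
  r <- gtm_e_step(model, matrix(subject_row, nrow = 1L))$R
  new_map_layer(model$grid, as.numeric(r), "probability", "grey_red")
}

#' Export / import a map layer as CSV
#'
#' Long format with columns `node_index`, `row`, `col`, `value`, `kind`,
#' `scheme`, `side`. Values are written with 17 significant digits so a
#' re-load reproduces the vector exactly.
#'
#' @param layer a `map_layer`.
#' @param path CSV path.
#' @return `write_map_csv()` returns the path invisibly; `read_map_csv()`
#'   the layer.
#' @export
write_map_csv <- function(layer, path) {
  out <- data.frame(node_index = seq_along(layer$values),
                    row = layer$row, col = layer$col,
                    value = num_format(layer$values),
                    kind = layer$kind, scheme = layer$scheme,
                    side = layer$side)
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' @rdname write_map_csv
#' @export
read_map_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(value = "character"))
  grid <- list(side = tab$side[1L], K = nrow(tab),
               row = tab$row, col = tab$col)
  vals <- suppressWarnings(as.numeric(tab$value))
  vals[is.na(tab$value) | tab$value == ""] <- NA_real_
  new_map_layer(grid, vals, tab$kind[1L], tab$scheme[1L])
}

# Linear colour ramp between two hex colours; t in [0, 1].
ramp_hex <- function(from, to, t) {
  a <- grDevices::col2rgb(from)
  b <- grDevices::col2rgb(to)
  m <- round(a %*% t(1 - t) + b %*% t(t))
  grDevices::rgb(m[1, ], m[2, ], m[3, ], maxColorValue = 255)
}

#' Render a map layer to SVG
#'
#' Draws the lattice as a grid of coloured circles: light grey to red for
#' layers derived from modelling (membership, reference, probability), light
#' grey to teal for investigative layers; undefined nodes are rendered in a
#' neutral tone. Marker size can optionally encode micro-cluster occupancy.
#' Output bytes are deterministic for a fixed layer.
#'
#' @param layer a `map_layer`.
#' @param path output `.svg` path.
#' @param size_by optional `map_layer` of kind `"membership"` whose counts
#'   scale the marker radii.
#' @param cell pixel size of one lattice cell (default 20).
#' @return The path, invisibly.
#' @export
render_map <- function(layer, path, size_by = NULL, cell = 20) {
  lo <- "#D9D9D9"
  hi <- switch(layer$scheme, grey_teal = "#0F8080", "#B2182B")
  v <- layer$values
  rng <- range(v, na.rm = TRUE)
  t <- if (diff(rng) > 0) (v - rng[1]) / diff(rng) else rep(0.5, length(v))
  cols <- rep("#F2F2F2", length(v))  # neutral for undefined nodes
  ok <- !is.na(v)
  cols[ok] <- ramp_hex(lo, hi, t[ok])
  rad <- rep(cell * 0.42, length(v))
  if (!is.null(size_by)) {
    s <- size_by$values
    smax <- max(s, na.rm = TRUE)
    if (smax > 0) rad <- cell * (0.12 + 0.36 * sqrt(pmax(s, 0) / smax))
  }
  w <- layer$side * cell
  lines <- c(
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
            w, w, w, w),
    sprintf('<rect width="%d" height="%d" fill="#FFFFFF"/>', w, w),
    sprintf('<!-- kind=%s scheme=%s side=%d -->', layer$kind, layer$scheme,
            layer$side),
    sprintf('<circle cx="%.2f" cy="%.2f" r="%.2f" fill="%s"/>',
            (layer$col - 0.5) * cell, (layer$row - 0.5) * cell, rad, cols),
    "</svg>")
  if (!dir.exists(dirname(path))) stop("cannot write to: ", path)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}
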