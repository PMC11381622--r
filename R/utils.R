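# Internal numerical helpers shared across modules.

# Row-wise log(sum(exp(m))) with max-shift stabilisation.
logsumexp_rows <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

# N x K matrix of squared Euclidean distances between rows of x and rows of y.
squared_distances <- function(x, y) {
  d <- outer(rowSums(x^2), rowSums(y^2), `+`) - 2 * tcrossprod(x, y)
  d[d < 0] <- 0
  d
}

# Moment-based sample skewness m3 / m2^(3/2); NA values dropped.
sample_skewness <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3L) {
    return(NA_real_)
  }
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= .Machine$double.eps) {
    return(0)
  }
  mean((x - m)^3) / m2^1.5
}

# Format doubles so that as.numeric() round-trips them bit-exactly (17
# significant digits is sufficient for IEEE-754 binary64).
num_format <- function(x) {
  out <- formatC(x, digits = 17L, format = "g")
  out[is.na(x)] <- NA_character_
  out
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", null = "null")
  invisible(path)
}

read_json_file <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

# md5 of the canonical JSON serialisation of a config list; used to stamp
# artifacts so a run can be traced back to the exact settings that made it.
config_hash <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
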