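# Internal helpers shared across modules.

#' Derive a reproducible 31-bit seed from a base seed and trial identifiers
#'
#' Mixes the base seed with arbitrary string/numeric identifiers through a
#' polynomial hash modulo the Mersenne prime 2^31 - 1, so that per-trial
#' random streams (e.g. the reference points of [memory_score()]) are
#' reproducible given the global seed yet uncorrelated across trials.
#'
#' @param seed integer base seed.
#' @param ... identifiers (character or numeric scalars) to mix in.
#' @return a single non-negative integer < 2^31 - 1.
#' @export
derive_seed <- function(seed, ...) {
  mod <- 2147483647
  h <- as.numeric(seed) %% mod
  for (p in list(...)) {
    if (is.character(p)) {
      for (ch in utf8ToInt(paste(p, collapse = "|"))) {
        h <- (h * 31 + ch) %% mod
      }
    } else {
      for (v in as.numeric(p)) {
        h <- (h * 31 + (abs(v) * 1000) %% mod) %% mod
      }
    }
    h <- (h * 131 + 17) %% mod
  }
  as.integer(h)
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Uniform points on a disk: r = R * sqrt(u) corrects for the area element.
runif_disk <- function(n, center = c(0, 0), radius = 1) {
  r <- radius * sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  cbind(x = center[1] + r * cos(th), y = center[2] + r * sin(th))
}

# Rotate points (n x 2) counterclockwise by `angle` radians about `center`.
rotate_points <- function(xy, angle, center = c(0, 0)) {
  xy <- rbind(xy)
  ca <- cos(angle); sa <- sin(angle)
  dx <- xy[, 1] - center[1]
  dy <- xy[, 2] - center[2]
  cbind(center[1] + ca * dx - sa * dy, center[2] + sa * dx + ca * dy)
}

deg2rad <- function(deg) deg * pi / 180

# Format numerics losslessly for CSV round-trips.
fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else formatC(v, digits = 17, format = "g")
  }, character(1))
  out
}

# Write a data.frame as RFC-4180 CSV with lossless numeric formatting and
# missing values as empty fields.
write_tidy_csv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) out[[j]] <- fmt_num(out[[j]])
    out[[j]][is.na(out[[j]])] <- ""
  }
  utils::write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE,
                     na = "", eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

read_tidy_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"),
                  fileEncoding = "UTF-8")
}
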