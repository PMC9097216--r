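#' @importFrom rlang abort warn inform %||% .data
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map_dbl map2 pmap imap list_rbind
#' @importFrom stats sd var qnorm pnorm pt quantile rnorm runif fft lm coef
#'   p.adjust aov median complete.cases setNames
#' @importFrom utils head tail modifyList
NULL

# Deterministic 31-bit sub-stream seed from a base seed plus string labels.
# Every random draw in the package goes through one of these named streams so
# that a single top-level seed makes a whole run bit-reproducible. All
# products stay below 2^53 so the modular arithmetic is exact in doubles.
substream_seed <- function(seed, ...) {
  m <- 2147483647
  h <- abs(as.numeric(seed)) %% m
  for (code in c(utf8ToInt(paste(c(...), collapse = "/")), 46L)) {
    h <- (h * 69621 + code) %% m
  }
  h <- (h * 48271 + 12345) %% m
  as.integer(h)
}

with_stream <- function(seed, ..., expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, ...))
  expr
}

sway_log <- function(level = c("INFO", "WARN", "ERROR"), ...) {
  level <- match.arg(level)
  message(sprintf("[%s] %s", level, paste0(...)))
}

`%|na|%` <- function(x, y) ifelse(is.na(x), y, x)
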