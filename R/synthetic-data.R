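#' True parameter sets for the 1PL/2PL simulation design
#'
#' Constructs an `irt_parameters` object holding person abilities, item
#' difficulties, and item discriminations on the logit scale. Under the 1PL
#' model every discrimination equals 1 exactly.
#'
#' @param theta numeric vector of abilities (length S).
#' @param b numeric vector of difficulties (length L).
#' @param a positive numeric vector of discriminations (length L); for the
#'   1PL model this must be `rep(1, L)`.
#' @param model `"1PL"` or `"2PL"`.
#' @return An object of class `irt_parameters`.
#' @export
irt_parameters <- function(theta, b, a = rep(1, length(b)),
                           model = c("1PL", "2PL")) {
  model <- match.arg(model)
  theta <- as.numeric(theta)
  b <- as.numeric(b)
  a <- as.numeric(a)
  if (length(a) != length(b)) {
    stop("discriminations and difficulties must have the same length")
  }
  if (any(!is.finite(theta)) || any(!is.finite(b)) || any(!is.finite(a))) {
    stop("parameters must be finite")
  }
  if (any(a <= 0)) stop("discriminations must be strictly positive")
  if (model == "1PL" && any(a != 1)) {
    stop("1PL requires all discriminations equal to 1")
  }
  structure(list(theta = theta, b = b, a = a, model = model),
            class = "irt_parameters")
}

#' @export
print.irt_parameters <- function(x, ...) {
  cat(sprintf("irt_parameters: %s, %d persons x %d items\n",
              x$model, length(x$theta), length(x$b)))
  invisible(x)
}

#' Draw true parameters for a simulated test
#'
#' Abilities and difficulties are drawn iid from the standard normal
#' distribution; 2PL discriminations are drawn iid lognormal with log-mean 0
#' and log-standard-deviation 0.25 (so the median discrimination is 1).
#' Under the 1PL model all discriminations are fixed at 1.
#'
#' @param S number of persons (>= 2).
#' @param L number of items (>= 2).
#' @param model `"1PL"` or `"2PL"`.
#' @param seed integer seed; the draw is reproducible given the seed.
#' @return An [irt_parameters] object.
#' @examples
#' p <- draw_parameters(100, 10, "2PL", seed = 1)
#' range(p$a) # positive slopes around 1
#' @export
draw_parameters <- function(S, L, model = c("1PL", "2PL"), seed) {
  model <- match.arg(model)
  if (!is.numeric(S) || !is.numeric(L) || S < 2 || L < 2 ||
      S != round(S) || L != round(L)) {
    stop("invalid design: S and L must be integers >= 2")
  }
  set.seed(seed)
  theta <- rnorm(S)
  b <- rnorm(L)
  a <- if (model == "2PL") rlnorm(L, meanlog = 0, sdlog = 0.25) else rep(1, L)
  irt_parameters(theta, b, a, model)
}

#' Simulate a binary response matrix
#'
#' Each response is 1 exactly when an independent Uniform(0,1) threshold
#' falls below the model probability [irf] of a correct answer.
#'
#' @param params an [irt_parameters] object.
#' @param seed integer seed.
#' @return An integer S x L matrix of class `irt_responses` with values in
#'   \{0, 1\} and `person`/`item` dimnames.
#' @export
simulate_responses <- function(params, seed) {
  stopifnot(inherits(params, "irt_parameters"))
  S <- length(params$theta)
  L <- length(params$b)
  set.seed(seed)
  P <- irf_matrix(params$theta, params$b, params$a)
  U <- matrix(runif(S * L), S, L)
  Y <- matrix(as.integer(U < P), S, L,
              dimnames = list(paste0("P", seq_len(S)),
                              paste0("I", seq_len(L))))
  class(Y) <- c("irt_responses", class(Y))
  Y
}

#' @export
print.irt_responses <- function(x, ...) {
  cat(sprintf("irt_responses: %d persons x %d items, mean correct %.3f\n",
              nrow(x), ncol(x), mean(x)))
  invisible(x)
}

as_response_matrix <- function(data) {
  if (inherits(data, "irt_responses")) return(unclass(data))
  if (!is.matrix(data)) stop("responses must be a matrix")
  if (!all(data %in% c(0L, 1L))) stop("responses must be 0/1 with no missing")
  data
}

#' Write / read response matrices as headered CSV
#'
#' Rows are persons, columns are items; a leading `person` column carries the
#' person labels.
#'
#' @param data response matrix.
#' @param path file path.
#' @return `read_responses` returns an `irt_responses` matrix.
#' @export
write_responses <- function(data, path) {
  m <- as_response_matrix(data)
  df <- data.frame(person = rownames(m) %||% paste0("P", seq_len(nrow(m))),
                   m, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_responses
#' @export
read_responses <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1]]
  if (!all(m %in% c(0L, 1L))) stop("response CSV must contain only 0/1")
  class(m) <- c("irt_responses", class(m))
  m
}

#' Write / read true parameters as long CSV
#'
#' Columns: `kind` (ability/difficulty/discrimination), `index`, `value`.
#'
#' @param params an [irt_parameters] object.
#' @param path file path.
#' @export
write_parameters <- function(params, path) {
  stopifnot(inherits(params, "irt_parameters"))
  df <- rbind(
    data.frame(kind = "ability", index = seq_along(params$theta),
               value = params$theta),
    data.frame(kind = "difficulty", index = seq_along(params$b),
               value = params$b),
    data.frame(kind = "discrimination", index = seq_along(params$a),
               value = params$a))
  df$model <- params$model
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_parameters
#' @export
read_parameters <- function(path) {
  df <- read.csv(path)
  irt_parameters(theta = df$value[df$kind == "ability"],
                 b = df$value[df$kind == "difficulty"],
                 a = df$value[df$kind == "discrimination"],
                 model = df$model[1])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
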