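# Degree-distribution histograms, shuffled-network null models and
# exponential / power-law least-squares fits with linear-scale R-squared.

#' Degree histogram with constant bin width
#'
#' Histogram of binary-connection degrees (a DN counts as connected to
#' another iff the pair is retained at the synapse threshold). Zero-degree
#' DNs fall in the first bin; bins are left-closed (`[0,5)`, `[5,10)`, ...).
#'
#' @param graph a `dn_graph`.
#' @param kind `"out"` (number of downstream DNs, the default), `"in"` or
#'   `"total"`.
#' @param bin_width constant bin width in neurons (default 5).
#' @return tibble of class `degree_histogram` with `bin_left`, `bin_right`,
#'   `centre`, `count`; attributes `kind`, `bin_width`, `degrees`.
#' @export
degree_histogram <- function(graph, kind = c("out", "in", "total"),
                             bin_width = 5) {
  kind <- match.arg(kind)
  deg <- dn_degree(graph)
  d <- switch(kind, out = deg$out_degree, `in` = deg$in_degree,
              total = deg$total_degree)
  edges <- seq(0, (max(d) %/% bin_width + 1) * bin_width, by = bin_width)
  counts <- tabulate(findInterval(d, edges), nbins = length(edges) - 1)
  out <- tibble(
    bin_left = edges[-length(edges)],
    bin_right = edges[-1],
    centre = (edges[-length(edges)] + edges[-1]) / 2,
    count = as.integer(counts)
  )
  structure(out, class = c("degree_histogram", class(out)),
            kind = kind, bin_width = bin_width, degrees = d)
}

#' Shuffled-network null model
#'
#' Rewires the graph while preserving the node count and the directed edge
#' count exactly: the retained edges are reassigned to uniformly sampled
#' distinct (pre, post) slots, with no self-loops and no duplicate pairs.
#' In the synapse-preserving mode (the clustering null) each original edge's
#' synapse count, neurotransmitter and sign travel with it to its new slot;
#' otherwise shuffled edges carry the graph's threshold count and an unknown
#' transmitter (a binary-connectivity null).
#'
#' @param graph a `dn_graph`.
#' @param seed integer seed (required, for reproducibility).
#' @param preserve_synapses logical (default `TRUE`).
#' @return a `dn_graph` with the same nodes and shuffled edges.
#' @export
shuffle_connections <- function(graph, seed, preserve_synapses = TRUE) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  ids <- graph$nodes$root_id
  n <- length(ids)
  n_edges <- nrow(graph$edges)
  if (n_edges > n * (n - 1)) {
    abort("more edges than available ordered pairs; cannot shuffle")
  }
  set.seed(as.integer(seed))
  slot <- sample(n * (n - 1), n_edges)
  i <- (slot - 1) %/% (n - 1) + 1
  r <- (slot - 1) %% (n - 1) + 1
  j <- r + (r >= i)
  if (preserve_synapses) {
    edges <- tibble(pre = ids[i], post = ids[j],
                    syn_count = graph$edges$syn_count,
                    nt = graph$edges$nt)
    edges$sign <- graph$edges$sign
    edges$sign_class <- graph$edges$sign_class
  } else {
    edges <- tibble(pre = ids[i], post = ids[j],
                    syn_count = as.integer(graph$min_synapses),
                    nt = "unknown",
                    sign = NA_real_, sign_class = "excluded")
  }
  out <- graph
  out$edges <- edges
  out$neuropil <- tibble(pre = edges$pre, post = edges$post,
                         neuropil = "unspecified",
                         syn_count = edges$syn_count)
  out
}

r_squared <- function(observed, predicted) {
  ss_res <- sum((observed - predicted)^2)
  ss_tot <- sum((observed - mean(observed))^2)
  1 - ss_res / ss_tot
}

#' Fit an exponential or power-law model to a degree histogram
#'
#' Least-squares fit of `a * exp(-b * x)` or `a * x^(-b)` to the bin counts
#' at the bin centres, on the linear scale (not log-log). Fit quality is the
#' linear-regression R-squared on counts, `1 - SS_res / SS_tot`, which can
#' be negative for a poor model. Starting values come from a log-linear
#' regression on the non-empty bins.
#'
#' @param hist a [degree_histogram()].
#' @param model `"exponential"` or `"power_law"`.
#' @return object of class `degree_fit` with `model`, `params` (`a`, `b`),
#'   `r_squared`, `fitted`, and the histogram data. Has [tidy()] and
#'   [glance()] methods.
#' @export
fit_degree_distribution <- function(hist, model = c("exponential", "power_law")) {
  model <- match.arg(model)
  x <- hist$centre
  y <- as.numeric(hist$count)
  if (sum(y > 0) < 3) abort("need at least 3 non-empty bins to fit")
  pos <- y > 0
  if (model == "exponential") {
    init <- lm(log(y[pos]) ~ x[pos])
    start <- list(a = exp(unname(coef(init)[1])), b = -unname(coef(init)[2]))
    form <- y ~ a * exp(-b * x)
  } else {
    init <- lm(log(y[pos]) ~ log(x[pos]))
    start <- list(a = exp(unname(coef(init)[1])), b = -unname(coef(init)[2]))
    form <- y ~ a * x^(-b)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = list(x = x, y = y), start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) {
      abort(sprintf("fit did not converge (last start a=%.4g, b=%.4g): %s",
                    start$a, start$b, conditionMessage(e)))
    }
  )
  p <- coef(fit)
  fitted_y <- predict(fit, newdata = list(x = x))
  structure(
    list(model = model, params = c(a = unname(p["a"]), b = unname(p["b"])),
         r_squared = r_squared(y, fitted_y),
         fitted = fitted_y, data = tibble(x = x, y = y)),
    class = "degree_fit"
  )
}

#' @export
print.degree_fit <- function(x, ...) {
  cat(sprintf("<degree_fit> %s: a = %.4g, b = %.4g, R^2 = %.4f\n",
              x$model, x$params["a"], x$params["b"], x$r_squared))
  invisible(x)
}

#' @export
tidy.degree_fit <- function(x, ...) {
  tibble(term = c("a", "b"), estimate = unname(x$params))
}

#' @export
glance.degree_fit <- function(x, ...) {
  tibble(model = x$model, r.squared = x$r_squared, nobs = nrow(x$data))
}

#' Compare two degree histograms by R-squared
#'
#' Treats the second histogram's counts as predictions of the first's and
#' returns `1 - SS_res / SS_tot`; a structureless predictor gives values
#' near or below zero. Requires identical binning.
#'
#' @param real_hist,other_hist [degree_histogram()] objects on the same bins.
#' @return numeric R-squared (can be negative).
#' @export
compare_distributions_r2 <- function(real_hist, other_hist) {
  if (!identical(attr(real_hist, "bin_width"), attr(other_hist, "bin_width"))) {
    abort("histograms have different bin widths")
  }
  n <- max(nrow(real_hist), nrow(other_hist))
  pad <- function(h) c(h$count, rep(0L, n - nrow(h)))
  y_real <- pad(real_hist)
  y_other <- pad(other_hist)
  r_squared(y_real, y_other)
}
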