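#' Fit an LDA topic model by collapsed Gibbs sampling
#'
#' Latent Dirichlet Allocation with symmetric Dirichlet priors, fitted by a
#' collapsed Gibbs sampler (compiled). Point estimates of the topic-word
#' matrix `phi` and document-topic matrix `theta` are taken from the final
#' sweep with the usual Dirichlet smoothing. The fit is deterministic given
#' `seed`.
#'
#' @param docs list of character vectors (tokenized documents); empty
#'   documents are dropped.
#' @param k number of topics (>= 1).
#' @param alpha document-topic concentration; default 50/k (a standard
#'   symmetric choice).
#' @param beta topic-word concentration; default 0.1.
#' @param n_iter Gibbs sweeps (default 200).
#' @param seed integer RNG seed.
#' @return Object of class `lda_model`: `phi` (k x V), `theta` (D x k),
#'   `vocab`, `docs_ids`, hyperparameters.
#' @export
lda_fit <- function(docs, k, alpha = 50 / k, beta = 0.1, n_iter = 200L,
                    seed = 1L) {
  stopifnot(k >= 1, alpha > 0, beta > 0)
  docs <- lapply(docs, as.character)
  docs <- docs[lengths(docs) > 0L]
  if (length(docs) == 0L) stop("no non-empty documents")
  vocab <- sort(unique(unlist(docs)))
  if (length(vocab) < 2L) stop("vocabulary too small for topic modelling")
  ids <- lapply(docs, function(d) match(d, vocab) - 1L)
  set.seed(seed)
  fit <- lda_gibbs_cpp(ids, length(vocab), as.integer(k),
                       alpha, beta, as.integer(n_iter))
  colnames(fit$phi) <- vocab
  structure(list(phi = fit$phi, theta = fit$theta, vocab = vocab,
                 docs_ids = ids, k = as.integer(k), alpha = alpha,
                 beta = beta, n_iter = as.integer(n_iter), seed = seed),
            class = "lda_model")
}

#' @export
print.lda_model <- function(x, ...) {
  cat(sprintf("LDA model: k = %d topics, V = %d words, D = %d documents\n",
              x$k, length(x$vocab), nrow(x$theta)))
  cat(sprintf("  alpha = %.3g, beta = %.3g, %d Gibbs sweeps, seed %d\n",
              x$alpha, x$beta, x$n_iter, x$seed))
  invisible(x)
}

#' Training perplexity of an LDA model
#'
#' `exp(-loglik / N)` where the token log-likelihood uses the point estimates
#' `theta %*% phi`. Computed on the training documents (held-in perplexity).
#'
#' @param model an `lda_model`.
#' @return Numeric scalar (lower is better).
#' @export
lda_perplexity <- function(model) {
  ll <- 0
  n_tok <- 0
  for (d in seq_along(model$docs_ids)) {
    wd <- model$docs_ids[[d]] + 1L
    pw <- as.numeric(model$theta[d, , drop = FALSE] %*%
                       model$phi[, wd, drop = FALSE])
    ll <- ll + sum(log(pw))
    n_tok <- n_tok + length(wd)
  }
  exp(-ll / n_tok)
}

#' Sliding-window NPMI topic coherence
#'
#' Word and word-pair probabilities are estimated from boolean sliding windows
#' (default width 10) over the corpus; a topic's coherence is the mean
#' normalized pointwise mutual information over all pairs of its `top_n`
#' words, and the model coherence is the mean over topics. Higher is more
#' coherent.
#'
#' @param model an `lda_model`.
#' @param docs the tokenized corpus (list of character vectors).
#' @param top_n words per topic entering the score (default 10).
#' @param window sliding-window width in tokens (default 10).
#' @return List with `coherence` (scalar) and `per_topic`.
#' @export
topic_coherence <- function(model, docs, top_n = 10L, window = 10L) {
  tops <- topic_keywords(model, top_n)
  cand <- unique(unlist(tops))
  wins <- list()
  for (d in docs) {
    d <- as.character(d)
    n <- length(d)
    if (n == 0L) next
    if (n <= window) {
      wins[[length(wins) + 1L]] <- unique(d)
    } else {
      for (s in seq_len(n - window + 1L)) {
        wins[[length(wins) + 1L]] <- unique(d[s:(s + window - 1L)])
      }
    }
  }
  n_win <- length(wins)
  if (n_win == 0L) stop("no windows: empty corpus")
  occ <- matrix(FALSE, nrow = n_win, ncol = length(cand),
                dimnames = list(NULL, cand))
  for (i in seq_len(n_win)) {
    hit <- intersect(wins[[i]], cand)
    if (length(hit) > 0L) occ[i, hit] <- TRUE
  }
  pw <- colMeans(occ)
  eps <- 1e-12
  per_topic <- vapply(tops, function(words) {
    words <- intersect(words, cand)
    if (length(words) < 2L) return(0)
    prs <- utils::combn(words, 2L)
    vals <- apply(prs, 2L, function(pr) {
      pij <- mean(occ[, pr[1]] & occ[, pr[2]])
      npmi <- log((pij + eps) / (pw[pr[1]] * pw[pr[2]] + eps)) /
        -log(pij + eps)
      unname(npmi)
    })
    mean(vals)
  }, numeric(1))
  list(coherence = mean(per_topic), per_topic = per_topic)
}

#' Top keywords per topic
#'
#' The `top_n` highest-probability words of each topic's word distribution,
#' in descending weight order. Requesting more words than the vocabulary
#' holds returns the full vocabulary with a warning.
#'
#' @param model an `lda_model`.
#' @param top_n keywords per topic (>= 1).
#' @return List of character vectors, one per topic.
#' @export
topic_keywords <- function(model, top_n = 10L) {
  stopifnot(top_n >= 1)
  V <- ncol(model$phi)
  if (top_n > V) {
    warning("top_n exceeds vocabulary size (", V, "); returning all words")
    top_n <- V
  }
  lapply(seq_len(nrow(model$phi)), function(k) {
    ord <- order(model$phi[k, ], decreasing = TRUE)[seq_len(top_n)]
    model$vocab[ord]
  })
}

#' Flag overlapping topic pairs
#'
#' Reports topic pairs whose topic-word distributions lie within a
#' Jensen-Shannon distance threshold -- a reproducible stand-in for judging
#' overlap on an intertopic 2-D projection. Flagged pairs are candidates for a
#' manual merge decision.
#'
#' @param model an `lda_model` with >= 2 topics.
#' @param threshold JS distance (base-2, in [0, 1]) below which a pair is
#'   flagged; default 0.25.
#' @return data.frame with columns `topic_a`, `topic_b`, `distance` (possibly
#'   zero rows).
#' @export
topic_overlap <- function(model, threshold = 0.25) {
  K <- nrow(model$phi)
  if (K < 2L) stop("need at least two topics")
  out <- data.frame(topic_a = integer(), topic_b = integer(),
                    distance = numeric())
  for (i in seq_len(K - 1L)) {
    for (j in seq((i + 1L), K)) {
      d <- js_distance(model$phi[i, ], model$phi[j, ])
      if (d < threshold) {
        out <- rbind(out, data.frame(topic_a = i, topic_b = j, distance = d))
      }
    }
  }
  out
}

# Jensen-Shannon distance with base-2 logs: sqrt(JSD) in [0, 1].
js_distance <- function(p, q) {
  p <- p / sum(p); q <- q / sum(q)
  m <- (p + q) / 2
  kl <- function(a, b) {
    nz <- a > 0
    sum(a[nz] * log2(a[nz] / b[nz]))
  }
  sqrt(pmax(0, (kl(p, m) + kl(q, m)) / 2))
}

#' Static intertopic distance plot
#'
#' Classical MDS of the pairwise Jensen-Shannon distances between topic-word
#' distributions, drawn with circle areas proportional to topic prevalence.
#'
#' @param model an `lda_model` with >= 2 topics.
#' @param file optional PNG path; when given, the plot is written there.
#' @return Invisibly, the 2-D coordinates.
#' @export
plot_intertopic <- function(model, file = NULL) {
  K <- nrow(model$phi)
  if (K < 2L) stop("need at least two topics")
  dm <- matrix(0, K, K)
  for (i in seq_len(K)) for (j in seq_len(K)) {
    if (i < j) dm[i, j] <- dm[j, i] <- js_distance(model$phi[i, ], model$phi[j, ])
  }
  xy <- stats::cmdscale(stats::as.dist(dm), k = min(2L, K - 1L))
  if (ncol(xy) == 1L) xy <- cbind(xy, 0)
  prev <- colMeans(model$theta)
  draw <- function() {
    graphics::plot(xy, xlab = "PC1", ylab = "PC2", asp = 1,
                   cex = 1 + 6 * prev / max(prev), pch = 1,
                   main = "Intertopic distance map (JS distance, MDS)")
    graphics::text(xy, labels = seq_len(K), pos = 3)
  }
  if (!is.null(file)) {
    grDevices::png(file, width = 640, height = 640)
    on.exit(grDevices::dev.off())
    draw()
  } else {
    draw()
  }
  invisible(xy)
}
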