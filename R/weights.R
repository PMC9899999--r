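#' Seven-domain ICN assignment table
#'
#' Assigns each ICN to one of the seven functional domains used for
#' weight-map summaries: subcortical (SC), auditory (AUD), visual (VS),
#' sensorimotor (SM), cognitive-control (CC), default-mode (DM) and
#' cerebellar (CB). For C = 53 the canonical template domain sizes are
#' used (SC 5, AUD 2, VS 9, SM 9, CC 17, DM 7, CB 4); for other C the
#' domains are assigned proportionally in the same order, so simulated
#' cohorts of any size carry a valid domain structure.
#'
#' @param n_icns Number of ICNs.
#' @param labels Optional ICN labels (default `ICN01`, ...).
#' @return Data frame with columns `icn` and `domain` (factor with the 7
#'   levels in canonical order).
#' @export
icn_domain_table <- function(n_icns = 53L, labels = NULL) {
  domains <- c("SC", "AUD", "VS", "SM", "CC", "DM", "CB")
  sizes53 <- c(SC = 5L, AUD = 2L, VS = 9L, SM = 9L, CC = 17L, DM = 7L,
               CB = 4L)
  if (n_icns < 7L) stop("need at least 7 ICNs for a seven-domain assignment")
  sizes <- if (n_icns == 53L) {
    sizes53
  } else {
    s <- pmax(1L, floor(sizes53 / 53 * n_icns))
    # distribute the remainder over the largest domains
    while (sum(s) < n_icns) s[which.max(sizes53 / 53 * n_icns - s)] <-
        s[which.max(sizes53 / 53 * n_icns - s)] + 1L
    while (sum(s) > n_icns) s[which.max(s)] <- s[which.max(s)] - 1L
    s
  }
  if (is.null(labels)) labels <- sprintf("ICN%02d", seq_len(n_icns))
  data.frame(icn = labels,
             domain = factor(rep(domains, sizes), levels = domains),
             stringsAsFactors = FALSE)
}

#' Aggregate fold-level coefficient maps
#'
#' Element-wise mean and standard deviation (n-1 denominator) over all
#' repetitions x folds coefficient vectors of a prediction run.
#'
#' @param result A [repeated_cv()] result with stored coefficient maps.
#' @return Data frame with columns `feature`, `mean_weight`, `sd_weight`;
#'   the number of maps averaged is attached as attribute `n_maps`.
#' @export
aggregate_weights <- function(result) {
  maps <- result$coefficient_maps
  if (is.null(maps) || nrow(maps) == 0L)
    stop("prediction result carries no coefficient maps")
  mw <- colMeans(maps)
  sw <- apply(maps, 2L, sd)
  out <- data.frame(
    feature = if (is.null(colnames(maps)))
      sprintf("f%04d", seq_along(mw)) else colnames(maps),
    mean_weight = mw, sd_weight = sw,
    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n_maps") <- nrow(maps)
  out
}

#' Domain-pair summary of a predictive weight map
#'
#' Splits the per-feature mean weights by the 7 x 7 grid of functional
#' domain pairs: positive and negative weights are summed separately per
#' pair, and each sum is divided by the number of connectivity features in
#' that pair, removing the influence of domain size. Dynamism features are
#' never folded into domain cells; summarize the static block only.
#'
#' @param weights Numeric vector of per-feature mean weights in the frozen
#'   pair order (length C(C-1)/2).
#' @param icn_domains Data frame from [icn_domain_table()] (every ICN
#'   assigned exactly one domain).
#' @return A list of class `domain_weight_summary`: `positive_cells`,
#'   `negative_cells` (7 x 7 symmetric, size-normalized; negative cells
#'   hold non-positive values), `pair_counts`, `domains`.
#' @export
domain_summary <- function(weights, icn_domains) {
  p <- length(weights)
  C <- (1 + sqrt(1 + 8 * p)) / 2
  if (C != round(C))
    stop("weight vector length is not C(C-1)/2 for any integer C")
  C <- as.integer(C)
  if (nrow(icn_domains) != C)
    stop("domain table does not cover every ICN")
  if (anyNA(icn_domains$domain)) stop("unassigned ICN in domain table")
  domains <- levels(icn_domains$domain)
  nd <- length(domains)
  pairs <- upper_pair_index(C)
  di <- as.integer(icn_domains$domain)[pairs$i]
  dj <- as.integer(icn_domains$domain)[pairs$j]
  lo <- pmin(di, dj); hi <- pmax(di, dj)
  pos <- matrix(0, nd, nd, dimnames = list(domains, domains))
  neg <- matrix(0, nd, nd, dimnames = list(domains, domains))
  cnt <- matrix(0L, nd, nd, dimnames = list(domains, domains))
  for (f in seq_len(p)) {
    w <- weights[f]
    cnt[lo[f], hi[f]] <- cnt[lo[f], hi[f]] + 1L
    if (w > 0) pos[lo[f], hi[f]] <- pos[lo[f], hi[f]] + w
    else if (w < 0) neg[lo[f], hi[f]] <- neg[lo[f], hi[f]] + w
  }
  norm <- function(m) {
    m <- ifelse(cnt > 0L, m / pmax(cnt, 1L), 0)
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    m
  }
  pos_n <- norm(pos); neg_n <- norm(neg)
  cnt[lower.tri(cnt)] <- t(cnt)[lower.tri(cnt)]
  structure(list(positive_cells = pos_n, negative_cells = neg_n,
                 pair_counts = cnt, domains = domains),
            class = "domain_weight_summary")
}

#' Correlation between two predictive weight maps
#'
#' Pearson correlation across the per-feature weights of two prediction
#' tasks, with its parametric p-value; used to ask how much the predictive
#' anatomy of two outcomes overlaps.
#'
#' @param map_a,map_b Numeric weight vectors in identical feature order.
#' @return A list with `r`, `p` and `n_features`.
#' @export
weightmap_correlation <- function(map_a, map_b) {
  if (length(map_a) != length(map_b))
    stop("weight maps differ in length")
  if (sd(map_a) == 0 || sd(map_b) == 0)
    stop("constant weight map: correlation undefined")
  ht <- cor.test(map_a, map_b, method = "pearson")
  list(r = unname(ht$estimate), p = ht$p.value,
       n_features = length(map_a))
}

#' Ranked strongest-weight connections
#'
#' The top `k` positive and top `k` negative mean-weight features, as
#' ranked tables (the tabular analogue of a top-50 connectome plot).
#'
#' @param weights Data frame from [aggregate_weights()] (static block).
#' @param k Number of connections per sign (default 50).
#' @return A list of two data frames, `positive` and `negative`, ordered
#'   by weight magnitude.
#' @export
top_connections <- function(weights, k = 50L) {
  ord <- order(weights$mean_weight, decreasing = TRUE)
  pos <- weights[ord[seq_len(min(k, sum(weights$mean_weight > 0)))], ]
  ordn <- order(weights$mean_weight)
  neg <- weights[ordn[seq_len(min(k, sum(weights$mean_weight < 0)))], ]
  list(positive = pos[order(-pos$mean_weight), ],
       negative = neg[order(neg$mean_weight), ])
}
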