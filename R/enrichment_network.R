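#' Dichotomize a feature's abundance across samples
#'
#' A sample is "high-abundance" for the feature iff its value exceeds the
#' cross-sample median; ties at the median go to low. The rule feeding the
#' 2x2 odds-ratio table is not pinned down by its original citation, so the
#' median split is the package's documented reimplementation choice.
#'
#' @param values Numeric vector over >= 2 samples.
#' @return Integer 0/1 vector (1 = high-abundance).
#' @export
dichotomize <- function(values) {
  if (length(values) < 2) stop("need >= 2 samples")
  as.integer(values > median(values))
}

#' Odds ratio with Haldane-Anscombe correction
#'
#' `OR = (a d) / (b c)` for the 2x2 table of dichotomized abundance vs
#' metabotype: a = high-abundance & high-metabotype, b = high-abundance &
#' low-metabotype, c = low-abundance & high-metabotype, d = low-abundance &
#' low-metabotype. If any cell is zero, 0.5 is added to all four cells
#' before computing.
#'
#' @param a,b,c,d Non-negative counts, not all zero.
#' @return The odds ratio (finite and positive).
#' @export
odds_ratio <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0)) stop("counts must be non-negative")
  if (sum(cells) == 0) stop("empty 2x2 table")
  if (any(cells == 0)) cells <- cells + 0.5
  (cells[1] * cells[4]) / (cells[2] * cells[3])
}

#' Classify an enzyme by its metabotype odds ratio
#'
#' Categories (made mutually exclusive): enriched (OR > 2), associated
#' (1 < OR <= 2), other (0.5 <= OR <= 1), depleted (OR < 0.5). The
#' differential abundance score is `abs(log2(OR))`. The "associated set"
#' used by the network tests is enriched-or-associated, i.e. OR > 1.
#'
#' @param or_value Positive odds ratio.
#' @return List with `odds_ratio`, `da_score`, `category` and `associated`
#'   (logical, OR > 1).
#' @export
classify_enrichment <- function(or_value) {
  if (!is.finite(or_value) || or_value <= 0)
    stop("odds ratio must be positive and finite")
  category <- if (or_value > 2) "enriched"
  else if (or_value > 1) "associated"
  else if (or_value >= 0.5) "other"
  else "depleted"
  list(odds_ratio = or_value, da_score = abs(log2(or_value)),
       category = category, associated = or_value > 1)
}

#' Per-enzyme odds-ratio enrichment over a feature table
#'
#' Dichotomizes every enzyme's abundance across samples ([dichotomize()]),
#' forms the 2x2 table against the metabotype labels, and classifies the
#' Haldane-corrected odds ratio ([classify_enrichment()]).
#'
#' @param table Non-negative enzymes x samples matrix.
#' @param labels Per-sample metabotype labels ("low"/"high"); names must
#'   match the table's samples if present.
#' @return data.frame per enzyme: 2x2 cells, odds_ratio, da_score,
#'   category, associated.
#' @export
metabotype_odds_ratios <- function(table, labels) {
  table <- as.matrix(table)
  if (!is.null(names(labels))) {
    if (!setequal(names(labels), colnames(table)))
      stop("label names do not match the table's samples")
    labels <- labels[colnames(table)]
  }
  stopifnot(length(labels) == ncol(table),
            all(labels %in% c("low", "high")))
  hi <- labels == "high"
  rows <- lapply(seq_len(nrow(table)), function(i) {
    z <- dichotomize(table[i, ])
    a <- sum(z == 1 & hi); b <- sum(z == 1 & !hi)
    c_ <- sum(z == 0 & hi); d <- sum(z == 0 & !hi)
    cls <- classify_enrichment(odds_ratio(a, b, c_, d))
    data.frame(enzyme_id = rownames(table)[i] %||% sprintf("K%04d", i),
               a = a, b = b, c = c_, d = d,
               odds_ratio = cls$odds_ratio, da_score = cls$da_score,
               category = cls$category, associated = cls$associated,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Internal: parse a semicolon-joined reaction annotation data.frame into
# lists of substrate and product compound sets.
parse_annotation <- function(annotation) {
  stopifnot(all(c("enzyme_id", "substrates", "products") %in% names(annotation)))
  if (anyDuplicated(annotation$enzyme_id)) stop("enzyme IDs must be unique")
  split_set <- function(x) {
    out <- strsplit(x, ";", fixed = TRUE)
    lapply(out, function(v) unique(v[nzchar(v)]))
  }
  list(enzymes = annotation$enzyme_id,
       substrates = split_set(annotation$substrates),
       products = split_set(annotation$products))
}

#' Build the community metabolic network
#'
#' Nodes are enzymes; a directed edge u -> v exists iff some product of u,
#' outside the currency blacklist, is a substrate of v. Self-loops are
#' dropped; isolated enzymes are kept as nodes.
#'
#' @param annotation data.frame with columns enzyme_id, substrates,
#'   products (compound IDs semicolon-joined).
#' @param blacklist Character vector of currency compounds excluded from
#'   edge construction (default none).
#' @return An [igraph][igraph::igraph-package] directed graph; edges carry a
#'   `compounds` attribute with the mediating compound IDs.
#' @export
build_network <- function(annotation, blacklist = character()) {
  ann <- parse_annotation(annotation)
  n <- length(ann$enzymes)
  consumers <- new.env(parent = emptyenv())
  for (j in seq_len(n)) {
    for (cpd in setdiff(ann$substrates[[j]], blacklist)) {
      consumers[[cpd]] <- c(consumers[[cpd]], j)
    }
  }
  from <- integer(); to <- integer(); via <- character()
  for (i in seq_len(n)) {
    hits <- new.env(parent = emptyenv())
    for (cpd in setdiff(ann$products[[i]], blacklist)) {
      for (j in consumers[[cpd]]) {
        if (j != i) hits[[as.character(j)]] <- c(hits[[as.character(j)]], cpd)
      }
    }
    for (jc in ls(hits)) {
      from <- c(from, i); to <- c(to, as.integer(jc))
      via <- c(via, paste(sort(hits[[jc]]), collapse = ";"))
    }
  }
  g <- igraph::make_empty_graph(n = n, directed = TRUE)
  g <- igraph::set_vertex_attr(g, "name", value = ann$enzymes)
  if (length(from))
    g <- igraph::add_edges(g, rbind(from, to), compounds = via)
  g
}

#' Normalized betweenness centrality
#'
#' Fraction of all-pairs directed shortest paths (unweighted, endpoints
#' excluded, fractional credit among co-shortest paths) passing through each
#' node, normalized by (n-1)(n-2). Unreachable pairs contribute nothing.
#'
#' @param network Directed igraph graph.
#' @return Named numeric vector in \[0, 1\].
#' @export
betweenness_centrality <- function(network) {
  n <- igraph::vcount(network)
  if (n == 0) return(numeric(0))
  raw <- igraph::betweenness(network, directed = TRUE, weights = NULL)
  if (n < 3) return(setNames(rep(0, n), igraph::V(network)$name))
  raw / ((n - 1) * (n - 2))
}

#' Bin enzymes into centrality tiers
#'
#' Tertile split on betweenness rank: the lowest third is peripheral, the
#' middle third intermediate, the top third central. Ties (including
#' all-equal scores) break lexically by enzyme ID, making tier sizes
#' deterministic and ceiling(n/3)-balanced.
#'
#' @param scores Named numeric betweenness scores, n >= 3.
#' @return data.frame per enzyme: betweenness, rank (ascending), tier.
#' @export
centrality_tiers <- function(scores) {
  n <- length(scores)
  if (n < 3) stop("need >= 3 nodes to form three tiers")
  ids <- names(scores) %||% sprintf("K%04d", seq_len(n))
  o <- order(scores, ids)
  rank <- integer(n); rank[o] <- seq_len(n)
  tier <- c("peripheral", "intermediate", "central")[ceiling(3 * rank / n)]
  data.frame(enzyme_id = ids, betweenness = unname(scores), rank = rank,
             tier = tier, stringsAsFactors = FALSE)
}

#' Wilcoxon rank-sum comparison of centrality distributions
#'
#' Compares a topological score between metabotype-associated and
#' non-associated enzymes. Uses exact enumeration when both groups have at
#' most 10 members and there are no ties, otherwise the normal approximation
#' with midrank tie correction. `W` is the rank-sum of the associated group.
#'
#' @param scores Numeric scores per enzyme.
#' @param associated_flags Logical vector; both groups must be non-empty.
#' @return List with `W` and `p` (two-sided).
#' @export
compare_centrality <- function(scores, associated_flags) {
  stopifnot(length(scores) == length(associated_flags))
  x <- scores[associated_flags]
  y <- scores[!associated_flags]
  if (length(x) == 0 || length(y) == 0) stop("both groups must be non-empty")
  n1 <- length(x)
  if (length(unique(c(x, y))) == 1)
    return(list(W = n1 * length(y) / 2 + n1 * (n1 + 1) / 2, p = 1))
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && n1 <= 10 && length(y) <= 10
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = !exact))
  list(W = unname(wt$statistic) + n1 * (n1 + 1) / 2, p = wt$p.value)
}

#' Hypergeometric tier over-representation test
#'
#' For each centrality tier, the upper-tail probability that at least the
#' observed number of associated enzymes falls in the tier:
#' `P[X >= k]`, X ~ Hypergeometric(N total, K associated, n tier size).
#'
#' @param tiers Character tier per enzyme (e.g. from [centrality_tiers()]).
#' @param associated_flags Logical vector over the same enzymes.
#' @return data.frame per tier: size, n_associated, expected, p_over.
#' @export
tier_enrichment <- function(tiers, associated_flags) {
  stopifnot(length(tiers) == length(associated_flags))
  N <- length(tiers)
  K <- sum(associated_flags)
  out <- lapply(unique(tiers), function(tn) {
    in_tier <- tiers == tn
    n <- sum(in_tier)
    k <- sum(associated_flags & in_tier)
    data.frame(tier = tn, size = n, n_associated = k,
               expected = K * n / N,
               p_over = phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Spearman correlation of differential-abundance score vs topology
#'
#' Rank correlation on midranks with a p-value from the t approximation.
#'
#' @param da_scores,topology_feature Paired numeric vectors, n >= 3.
#' @return List with `rho` and `p`.
#' @export
score_topology_correlation <- function(da_scores, topology_feature) {
  if (length(da_scores) != length(topology_feature))
    stop("vectors must be paired")
  if (length(da_scores) < 3) stop("need n >= 3")
  if (sd(rank(da_scores)) == 0 || sd(rank(topology_feature)) == 0)
    stop("zero rank variance")
  ct <- suppressWarnings(cor.test(da_scores, topology_feature,
                                  method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}
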