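# Independent oracles used by the dual-route checks. These deliberately do
# not share code with the package implementation.

# Brute-force betweenness: enumerate every path between every ordered pair
# by depth-first search, keep the shortest ones, and credit interior nodes
# fractionally. adj is a list: adj[[u]] = integer vector of out-neighbours.
brute_betweenness <- function(adj) {
  n <- length(adj)
  btw <- numeric(n)
  all_paths <- function(u, target, visited) {
    if (u == target) return(list(visited))
    out <- list()
    for (v in adj[[u]]) {
      if (!v %in% visited) out <- c(out, all_paths(v, target, c(visited, v)))
    }
    out
  }
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == t) next
    paths <- all_paths(s, t, s)
    if (!length(paths)) next
    lens <- vapply(paths, length, 0L)
    shortest <- paths[lens == min(lens)]
    sigma <- length(shortest)
    for (p in shortest) {
      interior <- p[-c(1, length(p))]
      btw[interior] <- btw[interior] + 1 / sigma
    }
  }
  if (n >= 3) btw / ((n - 1) * (n - 2)) else rep(0, n)
}

# Random directed graph as an adjacency list (no self-loops).
random_digraph <- function(n, p_edge) {
  adj <- vector("list", n)
  for (u in seq_len(n)) {
    nb <- setdiff(seq_len(n), u)
    adj[[u]] <- nb[runif(length(nb)) < p_edge]
  }
  adj
}

adj_to_igraph <- function(adj) {
  n <- length(adj)
  el <- do.call(rbind, lapply(seq_len(n), function(u)
    if (length(adj[[u]])) cbind(u, adj[[u]]) else NULL))
  g <- igraph::make_empty_graph(n = n, directed = TRUE)
  g <- igraph::set_vertex_attr(g, "name", value = sprintf("K%04d", seq_len(n)))
  if (!is.null(el)) g <- igraph::add_edges(g, t(el))
  g
}

# Brute-force network edges: all ordered enzyme pairs, literal set
# intersection of products and substrates after blacklist removal.
brute_network_edges <- function(subs, prods, blacklist = character()) {
  n <- length(subs)
  edges <- character()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    shared <- setdiff(intersect(prods[[i]], subs[[j]]), blacklist)
    if (length(shared)) edges <- c(edges, paste(i, j))
  }
  sort(edges)
}

# Random reaction annotation over a small compound alphabet.
random_annotation <- function(n_enzymes, n_compounds, set_size = 2) {
  cpds <- sprintf("C%02d", seq_len(n_compounds))
  subs <- replicate(n_enzymes, sample(cpds, set_size), simplify = FALSE)
  prods <- replicate(n_enzymes, sample(cpds, set_size), simplify = FALSE)
  list(
    df = data.frame(
      enzyme_id = sprintf("K%04d", seq_len(n_enzymes)),
      substrates = vapply(subs, paste, "", collapse = ";"),
      products = vapply(prods, paste, "", collapse = ";"),
      stringsAsFactors = FALSE),
    subs = subs, prods = prods)
}

# Labels used throughout: the emulated 16 low / 4 high design.
cohort_labels <- function(n_low = 16, n_high = 4) {
  setNames(c(rep("low", n_low), rep("high", n_high)),
           sprintf("S%02d", seq_len(n_low + n_high)))
}
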