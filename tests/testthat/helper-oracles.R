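# Shared fixtures and independent oracles used across the suite.

# The worked examples' name/ID pairs: a tiny name index covering the three
# illustrative SILVA records (snail, uncultured Fusibacter clone, nematode).
table1_records <- function() {
  data.frame(
    taxon_id = c(336503L, 76008L, 6231L, 2L, 2759L, 33208L, 1239L),
    name = c("Homalopoma granuliferum", "Fusibacter", "Nematoda",
             "Bacteria", "Eukaryota", "Metazoa", "Firmicutes"),
    name_class = "scientific name", stringsAsFactors = FALSE)
}

table1_entries <- function() {
  list(
    snail = silva_entry(
      "AB365303",
      c("Eukaryota", "Metazoa", "Turbinidae", "Homalopoma"),
      "Homalopoma granuliferum"),
    clone = silva_entry(
      "AY548990",
      c("Bacteria", "Firmicutes", "Family XII Incertae Sedis", "Fusibacter"),
      "uncultured bacterium"),
    nematode = silva_entry(
      "AY763126",
      c("Eukaryota", "Metazoa", "Nematoda", "environmental samples"),
      "uncultured nematode"))
}

# random rooted tree over n nodes (ids 1..n, root 1), ranks cycled
random_tree <- function(n, seed) {
  set.seed(seed)
  ids <- seq_len(n)
  parents <- c(1L, vapply(2:n, function(i) sample.int(i - 1L, 1), integer(1)))
  ranks <- c("no rank", rep_len(c("phylum", "class", "order", "family",
                                  "genus", "species"), n - 1L))
  taxonomy_tree(ids, parents, ranks)
}

# brute-force LCA: intersect full root paths, take the deepest member
lca_oracle <- function(tree, ids) {
  paths <- lapply(ids, function(id) ancestors_of(tree, id))
  common <- Reduce(intersect, paths)
  depth <- node_depths(tree)
  common[which.max(depth[as.character(common)])]
}

# naive min-support: sweep repeatedly until no non-root node is below the
# threshold, pushing one node per iteration
min_support_oracle <- function(profile, tree, min_support) {
  counts <- profile$counts
  depth <- node_depths(tree)
  root_key <- as.character(tree$root_id)
  repeat {
    keys <- names(counts)[counts > 0 & counts < min_support &
                            names(counts) != root_key]
    if (!length(keys)) break
    key <- keys[which.max(depth[keys])]
    parent_key <- as.character(tree$parent[[key]])
    counts[parent_key] <- (if (is.na(counts[parent_key])) 0
                           else counts[[parent_key]]) + counts[[key]]
    counts[key] <- 0
  }
  counts[counts > 0]
}

# exhaustive subtree-sum: for every node walk the whole tree and add counts
# of nodes whose root path contains it
summarize_oracle <- function(profile, tree) {
  keys <- names(tree$parent)
  out <- stats::setNames(rep(0, length(keys)), keys)
  for (node in keys) {
    for (counted in names(profile$counts)) {
      anc <- as.character(ancestors_of(tree, as.integer(counted)))
      if (node %in% anc) out[node] <- out[[node]] + profile$counts[[counted]]
    }
  }
  out
}

# random profile over a tree's nodes
random_profile <- function(tree, seed, n_taxa = 8, max_count = 12,
                           sample_id = "rand") {
  set.seed(seed)
  keys <- sample(names(tree$parent), min(n_taxa, length(tree$parent)))
  tax_profile(sample_id, stats::setNames(sample.int(max_count, length(keys),
                                                    replace = TRUE), keys))
}
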