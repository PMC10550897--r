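# Independent oracles and small fixture builders used across tests.

# brute-force connected components by union-find, independent of igraph
uf_components <- function(n_nodes, edge_a, edge_b) {
  parent <- seq_len(n_nodes)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (k in seq_along(edge_a)) {
    ra <- find(edge_a[k])
    rb <- find(edge_b[k])
    if (ra != rb) parent[rb] <- ra
  }
  vapply(seq_len(n_nodes), find, integer(1))
}

# random node/edge tables for network tests
random_graph_tables <- function(n_nodes = 30, edge_prob = 0.05) {
  genes <- sprintf("g%03d", seq_len(n_nodes))
  pairs <- which(upper.tri(matrix(TRUE, n_nodes, n_nodes)), arr.ind = TRUE)
  keep <- runif(nrow(pairs)) < edge_prob
  list(
    nodes = tibble::tibble(gene = genes, log2fc = rnorm(n_nodes)),
    edges = tibble::tibble(gene_a = genes[pairs[keep, 1]],
                           gene_b = genes[pairs[keep, 2]],
                           score = runif(sum(keep), 0.5, 1)))
}

# long-format readings for a set of per-sample, per-analyte triplicates
toy_readings <- function(values, sample_id = "S1", analyte = "cytA",
                         bead_count = 50) {
  tibble::tibble(sample_id = sample_id, analyte = analyte,
                 replicate = seq_along(values),
                 concentration_pg_ml = values, bead_count = bead_count)
}

# a noiseless OCR trace with explicitly chosen per-phase readings
manual_trace <- function(baseline, oligo, fccp, rot, well = "W1",
                         protein_ug = 10, treatment = "vehicle",
                         batch = "B1") {
  vals <- c(baseline, oligo, fccp, rot)
  phases <- rep(cytosig:::ocr_phases(),
                c(length(baseline), length(oligo), length(fccp), length(rot)))
  tibble::tibble(well = well, time_min = seq_along(vals) * 6.5, ocr = vals,
                 phase = factor(phases, levels = cytosig:::ocr_phases()),
                 protein_ug = protein_ug, treatment = treatment, batch = batch)
}
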