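# Shared fixtures, built in code at test time.

# deterministic token table covering all POS classes
make_tokens <- function(n = 12L, seed = 1L, words = NULL) {
  set.seed(seed)
  pos <- sample(c("noun", "verb", "adjective", "adverb", "other"), n,
                replace = TRUE)
  onset <- cumsum(runif(n, 0.05, 0.4))
  data.frame(
    token = if (is.null(words)) sprintf("w%02d", seq_len(n)) else
      rep_len(words, n),
    onset_s = onset,
    offset_s = onset + runif(n, 0.1, 0.6),
    pos = pos,
    syllables = sample(1:4, n, replace = TRUE),
    is_stop = pos == "other" & runif(n) < 0.5,
    stringsAsFactors = FALSE)
}

make_transcript <- function(...) aligned_transcript(make_tokens(...))

# tiny chain graph entity -> animal -> dog -> bulldog (+ a side branch)
toy_chain_graph <- function() {
  hypernym_graph(data.frame(
    child = c("animal", "dog", "bulldog", "cat"),
    parent = c("entity", "animal", "dog", "animal")))
}

# random hypernym DAG with <= n nodes: node i > 1 gets 1-2 parents among
# earlier nodes, so the root ("n1") is reachable and the graph is acyclic
random_dag <- function(n, seed) {
  set.seed(seed)
  edges <- do.call(rbind, lapply(2:n, function(i) {
    k <- 1L + (runif(1) < 0.3)
    data.frame(child = paste0("n", i),
               parent = paste0("n", sample.int(i - 1L, min(k, i - 1L))))
  }))
  hypernym_graph(edges, root = "n1")
}

# exhaustive min path length to root by DFS over all upward paths
enumerate_depth <- function(node, graph) {
  if (node == graph$root) return(0)
  parents <- graph$parents[[node]]
  if (is.null(parents)) return(Inf)
  1 + min(vapply(parents, enumerate_depth, numeric(1), graph = graph))
}

# small deterministic embedding table
make_embeddings <- function(words, dim = 5L, seed = 4L) {
  set.seed(seed)
  v <- matrix(rnorm(length(words) * dim), length(words), dim)
  rownames(v) <- words
  embedding_table(v)
}

# separable two-class data with informative leading features
make_classif_data <- function(n = 80L, p = 10L, seed = 1L, effect = 2) {
  set.seed(seed)
  y <- rep(0:1, length.out = n)
  X <- matrix(rnorm(n * p), n, p)
  X[, 1] <- X[, 1] + effect * y
  X[, 2] <- X[, 2] - effect * y
  colnames(X) <- paste0("f", seq_len(p))
  list(X = X, y = y)
}

# memoized audio cohort shared by the acoustic acceptance criteria
audio_cohort_cache <- new.env(parent = emptyenv())
acceptance_audio_cohort <- function() {
  if (is.null(audio_cohort_cache$cohort)) {
    audio_cohort_cache$cohort <- generate_cohort(cohort_config(
      n_patient = 25L, n_control = 25L, seed = 424242L,
      duration_s = 15, synthesize_audio = TRUE, snr_db = 20))
  }
  audio_cohort_cache$cohort
}
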