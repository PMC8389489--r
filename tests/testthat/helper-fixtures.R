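# Shared fixtures: tiny recordings and toy matrices built in code.

sine_recording <- function(freq, fs = 512, duration = 4, amp = 1,
                           n_channels = 1) {
  t <- (seq_len(fs * duration) - 1) / fs
  X <- matrix(rep(amp * sin(2 * pi * freq * t), n_channels),
              nrow = n_channels, byrow = TRUE)
  eeg_recording(X, fs = fs, channel_names = paste0("ch", seq_len(n_channels)))
}

rms <- function(x) sqrt(mean(x^2))

# Tiny epoched container wrapping raw per-epoch vectors (epochs x channels).
epochs_from_matrixlist <- function(mats, fs, w) {
  n_ep <- length(mats)
  C <- nrow(mats[[1]])
  len <- ncol(mats[[1]])
  ep <- array(NA_real_, c(n_ep, C, len),
              dimnames = list(NULL, rownames(mats[[1]]), NULL))
  for (e in seq_len(n_ep)) ep[e, , ] <- mats[[e]]
  structure(list(epochs = ep, w = w, fs = fs,
                 channel_names = rownames(mats[[1]]),
                 subject_id = "sx", trial_id = "tx", provenance = character()),
            class = "eeg_epochs")
}

# Independent brute-force BFS hop counts (no igraph) for the delta oracle.
bfs_hops <- function(adj) {
  n <- nrow(adj)
  H <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n); dist[s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (u in which(adj[v, ] == 1)) {
        if (dist[u] > dist[v] + 1) { dist[u] <- dist[v] + 1; queue <- c(queue, u) }
      }
    }
    H[s, ] <- dist
  }
  H
}

# Random connected graph on n nodes: random spanning tree plus extra edges.
random_connected_adj <- function(n, extra = n) {
  adj <- matrix(0L, n, n)
  for (v in 2:n) {
    u <- sample.int(v - 1, 1)
    adj[u, v] <- adj[v, u] <- 1L
  }
  for (k in seq_len(extra)) {
    uv <- sample.int(n, 2)
    adj[uv[1], uv[2]] <- adj[uv[2], uv[1]] <- 1L
  }
  diag(adj) <- 0L
  adj
}

# Run a short python script and capture stdout lines (sklearn/pywt oracles).
run_python <- function(code) {
  f <- tempfile(fileext = ".py")
  writeLines(code, f)
  on.exit(unlink(f))
  system2("python", f, stdout = TRUE, stderr = FALSE)
}
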