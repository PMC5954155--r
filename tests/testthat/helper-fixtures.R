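# Shared fixtures and independent oracles, built in code at test time.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, maker) {
  if (is.null(.fixture_cache[[key]])) assign(key, maker(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# A small but structurally complete screen for module tests.
tiny_config <- function(...) {
  sim_config(genome_length = 12000L, n_genes = 10L,
             n_bad_seeds = 4L, guides_per_bad_seed = 12L,
             n_offtarget_guides = 10L, depth_per_guide = 300,
             rng_seed = 7L, ...)
}

tiny_sim <- function() cached("tiny_sim", function() simulate_screen(tiny_config()))

tiny_fitness <- function() {
  cached("tiny_fitness", function() {
    sim <- tiny_sim()
    compute_log2fc(sim$counts, guides = sim$guides,
                   control_spacer = sim$config$control_spacer)
  })
}

# Independent PAM-scan oracle: regex with lookahead on the forward
# sequence; reverse-strand sites from the CC pattern.
pam_oracle <- function(sequence, circular = FALSE) {
  L <- nchar(sequence)
  s <- if (circular) paste0(sequence, substr(sequence, 1, 2)) else sequence
  fwd <- gregexpr("(?=.GG)", s, perl = TRUE)[[1]]
  fwd <- as.integer(fwd[fwd > 0]) - 1L            # 0-based N position
  rev_ <- gregexpr("(?=CC.)", s, perl = TRUE)[[1]]
  rev_ <- as.integer(rev_[rev_ > 0]) + 1L         # 0-based N position
  if (circular) {
    fwd <- unique(fwd %% L)
    rev_ <- unique(rev_ %% L)
  } else {
    fwd <- fwd[fwd + 2L <= L - 1L]
    rev_ <- rev_[rev_ <= L - 1L]
  }
  out <- rbind(data.frame(pam_pos = fwd, strand = rep("+", length(fwd))),
               data.frame(pam_pos = rev_, strand = rep("-", length(rev_))))
  out[order(out$pam_pos, out$strand), , drop = FALSE]
}

# Independent off-target oracle: regex search for seed+NGG on both strands.
offtarget_oracle <- function(genome, spacer, k, own_pam = NULL, own_strand = NULL) {
  seedk <- substr(spacer, 21L - k, 20L)
  s <- genome$sequence
  fwd_pat <- paste0("(?=", seedk, ".GG)")
  m <- gregexpr(fwd_pat, s, perl = TRUE)[[1]]
  m <- as.integer(m[m > 0])
  fwd <- (m - 1L) + k                              # 0-based N of the PAM
  rc_pat <- paste0("(?=CC.", revcomp(seedk), ")")
  m2 <- gregexpr(rc_pat, s, perl = TRUE)[[1]]
  m2 <- as.integer(m2[m2 > 0])
  rev_ <- (m2 - 1L) + 2L
  hits <- rbind(data.frame(pam_pos = fwd, strand = rep("+", length(fwd))),
                data.frame(pam_pos = rev_, strand = rep("-", length(rev_))))
  if (!is.null(own_pam))
    hits <- hits[!(hits$pam_pos == own_pam & hits$strand == own_strand), ,
                 drop = FALSE]
  hits[order(hits$pam_pos, hits$strand), , drop = FALSE]
}

random_genome <- function(len, circular = FALSE) {
  genome_record(paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                      collapse = ""), circular = circular)
}

# Exhaustive-search oracle for one variance-minimizing split.
split_oracle <- function(x, y, min_leaf) {
  o <- order(x); x <- x[o]; y <- y[o]
  n <- length(y)
  best <- NULL; best_sse <- sum((y - mean(y))^2) - 1e-12
  for (i in seq_len(n - 1L)) {
    if (i < min_leaf || n - i < min_leaf || x[i] == x[i + 1L]) next
    sse <- sum((y[1:i] - mean(y[1:i]))^2) +
      sum((y[(i + 1L):n] - mean(y[(i + 1L):n]))^2)
    if (sse < best_sse) {
      best_sse <- sse
      best <- (x[i] + x[i + 1L]) / 2
    }
  }
  best
}
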