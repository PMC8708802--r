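# Independent brute-force oracle for isotope envelopes: enumerate every
# isotopologue of a formula (all per-element multinomial allocations over
# isotopes), aggregate by integer neutron offset. Deliberately written with
# none of the package's convolution machinery; only the shared constants
# table is reused.
brute_force_pattern <- function(formula, n_peaks = 3L) {
  counts <- unclass(msipair::parse_formula(formula))
  tab <- msipair::isotope_table()

  # all ways to split n atoms over k isotope slots
  compositions <- function(n, k) {
    if (k == 1) return(matrix(n, ncol = 1))
    out <- list()
    for (i in 0:n) {
      rest <- compositions(n - i, k - 1)
      out[[length(out) + 1]] <- cbind(i, rest)
    }
    do.call(rbind, out)
  }

  per_element <- lapply(names(counts), function(el) {
    iso <- tab[tab$element == el, ]
    n <- counts[[el]]
    comp <- compositions(n, nrow(iso))
    logp <- apply(comp, 1, function(k) {
      lgamma(n + 1) - sum(lgamma(k + 1)) + sum(k * log(iso$abundance))
    })
    data.frame(
      offset = as.integer(comp %*% round(iso$mass - iso$mass[1])),
      mass = as.numeric(comp %*% iso$mass),
      prob = exp(logp))
  })

  combined <- Reduce(function(a, b) {
    idx <- expand.grid(i = seq_len(nrow(a)), j = seq_len(nrow(b)))
    data.frame(offset = a$offset[idx$i] + b$offset[idx$j],
               mass = a$mass[idx$i] + b$mass[idx$j],
               prob = a$prob[idx$i] * b$prob[idx$j])
  }, per_element)

  agg_p <- tapply(combined$prob, combined$offset, sum)
  agg_m <- tapply(combined$prob * combined$mass, combined$offset, sum) / agg_p
  off <- as.integer(names(agg_p))
  ord <- order(off)
  keep <- ord[off[ord] < n_peaks]
  p <- as.numeric(agg_p[keep])
  data.frame(offset = off[keep],
             mz_offset = as.numeric(agg_m[keep]) - agg_m[[which(off == 0)]],
             abundance = p / max(p))
}

# random CHNOPS formula with at most max_atoms atoms (always >= 1 carbon and
# 1 hydrogen so the molecule is lipid-plausible)
random_formula <- function(max_atoms = 30L) {
  repeat {
    n_c <- sample(1:12, 1)
    n_h <- sample(1:16, 1)
    n_n <- sample(0:2, 1)
    n_o <- sample(0:6, 1)
    n_p <- sample(0:1, 1)
    n_s <- sample(0:1, 1)
    if (n_c + n_h + n_n + n_o + n_p + n_s <= max_atoms) break
  }
  parts <- c(C = n_c, H = n_h, N = n_n, O = n_o, P = n_p, S = n_s)
  parts <- parts[parts > 0]
  paste0(names(parts), parts, collapse = "")
}

# tiny hand-built dataset: a rectangular grid with chosen peaks per pixel
toy_dataset <- function(peaks, nx = 3L, ny = 1L, polarity = "positive",
                        mz_window = c(150, 1800)) {
  coords <- expand.grid(x = 0:(nx - 1L), y = 0:(ny - 1L))
  msipair::msi_dataset(peaks, coords = coords, polarity = polarity,
                       mz_window = mz_window)
}
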