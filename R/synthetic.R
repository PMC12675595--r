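#' Configuration for the synthetic biased-DTI generator
#'
#' The generator emulates the statistical structure of public DTI training
#' sets: per-target and per-drug label propensities with optional extreme
#' bimodal concentration near 0 and 1 (the signature of target prior
#' tendency), mixed with an optional latent interaction mechanism that gives
#' debiasing methods a learnable ground truth.
#'
#' Defaults describe a strongly target-biased corpus: most targets carry an
#' extreme propensity while drugs stay near balance, the pattern the
#' prior-tendency audit is designed to detect.
#'
#' @param n_drugs,n_targets,n_pairs entity and pair counts;
#'   `n_pairs <= n_drugs * n_targets` and `n_pairs >= max(n_drugs, n_targets)`.
#' @param target_bias,drug_bias probability that a target (drug) receives an
#'   extreme propensity, in `[0, 1]`.
#' @param extreme_eps extreme propensities are `eps` and `1 - eps`, in (0, 0.5).
#' @param mechanism_weight mixing weight in `[0, 1]` between the latent
#'   interaction mechanism and the propensity label model.
#' @param latent_dim dimension of the per-entity latent vectors.
#' @param seq_len_range integer range of target sequence lengths.
#' @param target_comp_conc Dirichlet concentration of the family residue
#'   usage profiles; smaller values give families more distinctive bulk
#'   compositions.
#' @param targets_per_family number of targets sharing one composition
#'   profile (a "family"); targets within a family differ in residue order
#'   but not in bulk composition, so family membership is robust to residue
#'   subsampling while individual identity is not.
#' @param seed integer seed; the generated dataset is fully determined by it.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_drugs = 100L, n_targets = 50L, n_pairs = 1000L,
                             target_bias = 0.8, drug_bias = 0.1,
                             extreme_eps = 0.05, mechanism_weight = 0.5,
                             latent_dim = 8L, seq_len_range = c(30L, 60L),
                             target_comp_conc = 3, targets_per_family = 3L,
                             seed = 1L) {
  cfg <- list(n_drugs = as.integer(n_drugs), n_targets = as.integer(n_targets),
              n_pairs = as.integer(n_pairs), target_bias = target_bias,
              drug_bias = drug_bias, extreme_eps = extreme_eps,
              mechanism_weight = mechanism_weight,
              latent_dim = as.integer(latent_dim),
              seq_len_range = as.integer(seq_len_range),
              target_comp_conc = target_comp_conc,
              targets_per_family = as.integer(targets_per_family),
              seed = as.integer(seed))
  for (p in c("target_bias", "drug_bias", "mechanism_weight")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop_format("%s must lie in [0, 1]", p)
  }
  if (cfg$extreme_eps <= 0 || cfg$extreme_eps >= 0.5) {
    stop_format("extreme_eps must lie in (0, 0.5)")
  }
  if (cfg$n_pairs < max(cfg$n_drugs, cfg$n_targets)) {
    stop_format("n_pairs must be >= max(n_drugs, n_targets)")
  }
  if (cfg$n_pairs > cfg$n_drugs * cfg$n_targets) {
    stop_format("n_pairs exceeds the number of distinct (drug, target) pairs")
  }
  structure(cfg, class = "synthetic_config")
}

# SMILES-like strings from a tiny fragment grammar: enough token diversity
# for the tokenizer and encoder, chemical validity is not required here
random_smiles_one <- function() {
  atoms <- c("C", "C", "C", "N", "O", "c", "S", "F", "Cl", "Br")
  bonds <- c("", "", "", "=", "#")
  n <- sample(6:16, 1L)
  parts <- character(0)
  i <- 0L
  while (i < n) {
    u <- runif(1)
    if (u < 0.12) {
      parts <- c(parts, "c1ccccc1")
      i <- i + 6L
    } else if (u < 0.27 && i > 0L) {
      k <- sample(1:3, 1L)
      parts <- c(parts, "(", paste0(sample(bonds, k, TRUE), sample(atoms, k, TRUE),
                                    collapse = ""), ")")
      i <- i + k
    } else {
      parts <- c(parts, paste0(sample(bonds, 1L), sample(atoms, 1L)))
      i <- i + 1L
    }
  }
  paste(parts, collapse = "")
}

# each target draws its own residue-usage distribution from a Dirichlet, so
# targets differ in bulk composition (a robust, physicochemistry-like trait)
# and not merely in fine-scale sampling fluctuations
random_protein_one <- function(len_range, probs = NULL) {
  n <- sample(len_range[1L]:len_range[2L], 1L)
  paste(sample(AA20, n, replace = TRUE, prob = probs), collapse = "")
}

rdirichlet_one <- function(alpha, k) {
  g <- stats::rgamma(k, shape = alpha)
  g / sum(g)
}

#' Generate a synthetic biased DTI dataset
#'
#' Each target receives a label propensity that is extreme (`eps` or
#' `1 - eps`, coin flip) with probability `target_bias` and otherwise uniform
#' on (0.35, 0.65); drugs analogously with `drug_bias`. Pairs are drawn
#' uniformly without duplicates, and each label is Bernoulli with success
#' probability
#' `mechanism_weight * m(d, t) + (1 - mechanism_weight) * mean(theta_d, theta_t)`,
#' where the mechanism `m(d, t)` is 1 when the two entities' latent unit
#' vectors have positive dot product. The mechanism is thus a real pairwise
#' interaction rule a model can learn, while the propensity component is a
#' pure label shortcut.
#'
#' @param config a [synthetic_config()].
#' @return a [dti_dataset()]; byte-identical for equal configs.
#' @export
generate_synthetic <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    nd <- config$n_drugs
    nt <- config$n_targets
    smiles <- character(nd)
    seen <- new.env(hash = TRUE)
    for (i in seq_len(nd)) {
      repeat {
        s <- random_smiles_one()
        if (is.null(seen[[s]])) {
          seen[[s]] <- TRUE
          smiles[i] <- s
          break
        }
      }
    }
    sequences <- character(nt)
    seen_t <- new.env(hash = TRUE)
    n_fam <- max(1L, ceiling(nt / config$targets_per_family))
    fam_profiles <- lapply(seq_len(n_fam), function(f) {
      rdirichlet_one(config$target_comp_conc, length(AA20))
    })
    fam_of <- rep(seq_len(n_fam), length.out = nt)
    for (i in seq_len(nt)) {
      probs <- fam_profiles[[fam_of[i]]]
      repeat {
        s <- random_protein_one(config$seq_len_range, probs)
        if (is.null(seen_t[[s]])) {
          seen_t[[s]] <- TRUE
          sequences[i] <- s
          break
        }
      }
    }
    draw_propensity <- function(n, bias, eps) {
      extreme <- runif(n) < bias
      ifelse(extreme,
             ifelse(runif(n) < 0.5, eps, 1 - eps),
             runif(n, 0.35, 0.65))
    }
    theta_d <- draw_propensity(nd, config$drug_bias, config$extreme_eps)
    theta_t <- draw_propensity(nt, config$target_bias, config$extreme_eps)
    # Latent interaction vectors are seeded random projections of each
    # entity's observable composition (token / residue frequencies), centered
    # across the cohort and normalized: approximately spherical, yet a
    # deterministic function of the sequences, so the mechanism label can be
    # learned from the inputs rather than memorized per entity.
    project_unit <- function(comp, k) {
      comp <- scale(comp, center = TRUE, scale = FALSE)
      P <- matrix(stats::rnorm(ncol(comp) * k), ncol(comp), k)
      m <- comp %*% P
      m / pmax(sqrt(rowSums(m^2)), 1e-12)
    }
    char_comp <- function(strings, alphabet) {
      t(vapply(strsplit(strings, ""), function(ch) {
        tab <- table(factor(ch, levels = alphabet))
        as.numeric(tab) / length(ch)
      }, numeric(length(alphabet))))
    }
    drug_alphabet <- sort(unique(unlist(strsplit(smiles, ""))))
    u_d <- project_unit(char_comp(smiles, drug_alphabet), config$latent_dim)
    v_t <- project_unit(char_comp(sequences, AA20), config$latent_dim)
    # uniform draw over distinct (drug, target) cells
    cells <- sample.int(nd * nt, config$n_pairs)
    di <- ((cells - 1L) %% nd) + 1L
    ti <- ((cells - 1L) %/% nd) + 1L
    m_dt <- as.numeric(rowSums(u_d[di, , drop = FALSE] * v_t[ti, , drop = FALSE]) > 0)
    p <- config$mechanism_weight * m_dt +
      (1 - config$mechanism_weight) * (theta_d[di] + theta_t[ti]) / 2
    label <- as.integer(runif(config$n_pairs) < p)
    dti_dataset(
      smiles = smiles[di], sequence = sequences[ti], label = label,
      drug_id = sprintf("D%04d", di), target_id = sprintf("T%04d", ti)
    )
  })
}
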