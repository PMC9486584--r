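# Synthetic two-condition multi-omics fixtures with planted differential
# correlation structure, known drug targets and matching sensitivities.

#' Specification for a synthetic multi-omics fixture
#'
#' Describes a two-condition dataset with block-correlated features: every
#' layer shares the same feature names and block assignment (emulating the
#' mRNA-protein-phosphosite correspondence exploited by same-name
#' connectors), and features of one block load on a per-sample latent
#' factor so that the within-block correlation equals `within_cor`. In
#' condition B the first `n_perturbed` blocks are generated with
#' correlation `within_cor - cor_delta` instead — the planted differential
#' signal. Drugs target features of the chosen `target_layer`:
#' "differential" drugs target perturbed blocks and their sensitivities are
#' shifted by `sens_effect` standard deviations in condition A, "null"
#' drugs target unperturbed blocks with identical sensitivity
#' distributions.
#'
#' @param layers Named integer vector: features per layer.
#' @param n_samples Samples per condition.
#' @param n_blocks Number of correlated feature blocks per layer.
#' @param within_cor Within-block correlation in condition A, in \[0, 1).
#' @param cor_delta Correlation reduction of perturbed blocks in condition
#'   B; `within_cor - cor_delta` must stay >= 0 (the factor construction is
#'   otherwise infeasible).
#' @param n_perturbed Number of perturbed blocks.
#' @param connector_density Fraction of shared feature names connected
#'   between adjacent layers, in \[0, 1\].
#' @param n_drugs Number of drugs.
#' @param targets_per_drug Targets per drug.
#' @param frac_perturbed_targets Fraction of drugs targeting perturbed
#'   blocks.
#' @param sens_effect Sensitivity shift (in SD units) of differential drugs
#'   in condition A.
#' @param n_replicates Sensitivity replicates per drug and condition.
#' @param missing_frac Fraction of abundance entries set missing completely
#'   at random.
#' @param base_level,noise_sd Location and scale of the reported abundances
#'   (correlation structure is scale-invariant).
#' @param conditions Length-2 character vector of condition labels.
#' @param target_layer Layer from which drug targets are drawn.
#' @param seed Integer seed; a fixed seed makes every generated table
#'   reproducible.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(layers = c(mrna = 300L, protein = 300L, phosphosite = 300L),
                         n_samples = 40L,
                         n_blocks = 10L,
                         within_cor = 0.7,
                         cor_delta = 0.6,
                         n_perturbed = 5L,
                         connector_density = 1,
                         n_drugs = 50L,
                         targets_per_drug = 3L,
                         frac_perturbed_targets = 0.5,
                         sens_effect = 3,
                         n_replicates = 10L,
                         missing_frac = 0.05,
                         base_level = 10,
                         noise_sd = 1,
                         conditions = c("A", "B"),
                         target_layer = "protein",
                         seed = 1L) {
  if (is.null(names(layers)) || any(names(layers) == "")) abort("`layers` must be named.")
  if (within_cor < 0 || within_cor >= 1) abort("`within_cor` must lie in [0, 1).")
  if (within_cor - cor_delta < 0) {
    abort("Infeasible correlation: `within_cor - cor_delta` is negative.")
  }
  for (f in c("connector_density", "frac_perturbed_targets", "missing_frac")) {
    v <- get(f)
    if (v < 0 || v > 1) abort(paste0("`", f, "` must lie in [0, 1]."))
  }
  if (n_perturbed > n_blocks) abort("`n_perturbed` cannot exceed `n_blocks`.")
  if (target_layer %not_in% names(layers)) abort("`target_layer` must be one of the layers.")
  if (length(conditions) != 2L || conditions[1] == conditions[2]) {
    abort("`conditions` must be two distinct labels.")
  }
  structure(
    list(
      layers = layers, n_samples = as.integer(n_samples),
      n_blocks = as.integer(n_blocks), within_cor = within_cor,
      cor_delta = cor_delta, n_perturbed = as.integer(n_perturbed),
      connector_density = connector_density, n_drugs = as.integer(n_drugs),
      targets_per_drug = as.integer(targets_per_drug),
      frac_perturbed_targets = frac_perturbed_targets,
      sens_effect = sens_effect, n_replicates = as.integer(n_replicates),
      missing_frac = missing_frac, base_level = base_level, noise_sd = noise_sd,
      conditions = conditions, target_layer = target_layer, seed = as.integer(seed)
    ),
    class = "fixture_spec"
  )
}

block_assignment <- function(n_features, n_blocks) {
  sort(rep(seq_len(n_blocks), length.out = n_features))
}

#' Generate two-condition block-correlated omics matrices
#'
#' Within-block abundances follow a one-factor model
#' `x = sqrt(rho) * z_block + sqrt(1 - rho) * noise`, giving an exact
#' within-block population correlation of `rho`. The block latent factor is
#' shared across layers, so same-name features of the same block are also
#' correlated between layers. Perturbed blocks use
#' `rho = within_cor - cor_delta` in the second condition. A
#' `missing_frac` fraction of entries is set missing completely at random
#' to exercise pairwise-complete correlation.
#'
#' @param spec A [fixture_spec()].
#' @return A list with `omics` (per condition, a named list of
#'   [omics_matrix()] objects), `blocks` (tibble `layer`, `feature`,
#'   `block`) and `perturbed_blocks` (integer vector).
#' @export
generate_grouped_omics <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  withr::with_seed(spec$seed, {
    perturbed <- seq_len(spec$n_perturbed)
    blocks_by_layer <- purrr::imap(as.list(spec$layers), function(n, ln) {
      tibble(
        layer = rep(ln, n),
        feature = sprintf("F%04d", seq_len(n)),
        block = block_assignment(n, spec$n_blocks)
      )
    })
    omics <- stats::setNames(vector("list", 2L), spec$conditions)
    for (ci in 1:2) {
      rho_block <- rep(spec$within_cor, spec$n_blocks)
      if (ci == 2L) rho_block[perturbed] <- spec$within_cor - spec$cor_delta
      # block latents shared across layers within this condition
      z <- matrix(stats::rnorm(spec$n_blocks * spec$n_samples), spec$n_blocks)
      omics[[ci]] <- purrr::imap(as.list(spec$layers), function(n, ln) {
        b <- blocks_by_layer[[ln]]$block
        rho <- rho_block[b]
        eps <- matrix(stats::rnorm(n * spec$n_samples), n)
        x <- sqrt(rho) * z[b, , drop = FALSE] + sqrt(1 - rho) * eps
        vals <- spec$base_level + spec$noise_sd * x
        if (spec$missing_frac > 0) {
          vals[stats::runif(length(vals)) < spec$missing_frac] <- NA_real_
        }
        df <- as_tibble(as.data.frame(vals))
        names(df) <- sprintf("S%s%02d", spec$conditions[ci], seq_len(spec$n_samples))
        df <- dplyr::bind_cols(tibble(feature = blocks_by_layer[[ln]]$feature), df)
        omics_matrix(df, layer = ln, condition = spec$conditions[ci])
      })
    }
    list(
      omics = omics,
      blocks = dplyr::bind_rows(blocks_by_layer),
      perturbed_blocks = perturbed
    )
  })
}

#' Generate drug targets and sensitivities with planted signal
#'
#' Differential drugs draw their targets from perturbed blocks of the
#' target layer and get sensitivities shifted by `sens_effect` SD in the
#' first condition; null drugs target unperturbed blocks and share one
#' sensitivity distribution across conditions.
#'
#' @param spec A [fixture_spec()].
#' @param blocks Block-assignment tibble from [generate_grouped_omics()].
#' @return A list with `drug_targets` (tibble `drug_id`, `target_id`,
#'   `target_layer`), `sensitivities` (tibble `cell_line_id`, `condition`,
#'   `drug_id`, `sensitivity`) and `drug_info` (tibble `drug_id`,
#'   `differential`).
#' @export
generate_drug_data <- function(spec, blocks) {
  stopifnot(inherits(spec, "fixture_spec"))
  withr::with_seed(spec$seed + 1L, {
    pool <- blocks[blocks$layer == spec$target_layer, ]
    perturbed_pool <- pool$feature[pool$block <= spec$n_perturbed]
    null_pool <- pool$feature[pool$block > spec$n_perturbed]
    n_diff <- round(spec$n_drugs * spec$frac_perturbed_targets)
    if (spec$targets_per_drug > length(perturbed_pool) && n_diff > 0) {
      abort("More targets per drug requested than perturbed-block features available.")
    }
    if (spec$targets_per_drug > length(null_pool) && n_diff < spec$n_drugs) {
      abort("More targets per drug requested than unperturbed-block features available.")
    }
    drug_ids <- sprintf("drug%03d", seq_len(spec$n_drugs))
    differential <- seq_len(spec$n_drugs) <= n_diff
    targets <- dplyr::bind_rows(purrr::map(seq_len(spec$n_drugs), function(i) {
      src <- if (differential[i]) perturbed_pool else null_pool
      tibble(
        drug_id = drug_ids[i],
        target_id = sample(src, spec$targets_per_drug),
        target_layer = spec$target_layer
      )
    }))
    sens <- tidyr::expand_grid(
      drug_id = drug_ids,
      condition = spec$conditions,
      replicate = seq_len(spec$n_replicates)
    )
    shift <- ifelse(
      sens$drug_id %in% drug_ids[differential] & sens$condition == spec$conditions[1],
      spec$sens_effect, 0
    )
    sens$sensitivity <- stats::rnorm(nrow(sens), mean = shift, sd = 1)
    sens$cell_line_id <- sprintf("cl_%s_%02d", sens$condition, sens$replicate)
    list(
      drug_targets = targets,
      sensitivities = sens[, c("cell_line_id", "condition", "drug_id", "sensitivity")],
      drug_info = tibble(drug_id = drug_ids, differential = differential)
    )
  })
}

#' Connector specifications implied by a fixture
#'
#' Adjacent layers (in the order listed in the spec) are linked by
#' same-name connectors of weight 1; with `connector_density < 1` only a
#' random fraction of the shared names is connected, via an explicit pair
#' table.
#'
#' @param spec A [fixture_spec()].
#' @param blocks Block-assignment tibble from [generate_grouped_omics()].
#' @return A list of `connector_spec` objects.
#' @export
fixture_connectors <- function(spec, blocks) {
  stopifnot(inherits(spec, "fixture_spec"))
  lns <- names(spec$layers)
  if (length(lns) < 2L) {
    return(list())
  }
  withr::with_seed(spec$seed + 2L, {
    purrr::map(seq_len(length(lns) - 1L), function(i) {
      a <- lns[i]
      b <- lns[i + 1L]
      if (spec$connector_density >= 1) {
        return(connector_same_name(a, b, weight = 1))
      }
      shared <- intersect(
        blocks$feature[blocks$layer == a],
        blocks$feature[blocks$layer == b]
      )
      keep <- sample(shared, round(spec$connector_density * length(shared)))
      connector_pairs(tibble(
        layer_a = a, node_a = keep, layer_b = b, node_b = keep, weight = 1
      ))
    })
  })
}

#' Generate a complete synthetic fixture
#'
#' @param spec A [fixture_spec()].
#' @return A list combining [generate_grouped_omics()] and
#'   [generate_drug_data()] output, the implied connector list, and the
#'   spec itself.
#' @export
generate_fixture <- function(spec = fixture_spec()) {
  om <- generate_grouped_omics(spec)
  dr <- generate_drug_data(spec, om$blocks)
  c(om, dr, list(connectors = fixture_connectors(spec, om$blocks), spec = spec))
}
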