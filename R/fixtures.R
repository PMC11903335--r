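#' Fixture generation: synthetic multi-chain complexes
#'
#' The fixture generator builds protein-like C-alpha traces (compact
#' self-avoiding random walks with realistic 3.8 A consecutive spacing)
#' and assembles them into complex pairs with a *planted* ground truth:
#' the target complex is one global rigid transform of the query, with
#' chains renamed, permuted and perturbed by Gaussian coordinate noise.
#' All randomness flows from a single integer seed through one explicit
#' generator scope, so reruns are bit-identical and no global RNG state
#' leaks.
#'
#' @name fixtures
NULL

# run expr with a local, seeded RNG; the caller's RNG state is untouched
with_fixture_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Random protein-like chain
#'
#' Generates a compact self-avoiding random walk: consecutive C-alpha
#' spacing 3.8 +/- 0.05 A with bond-angle jitter (direction persistence),
#' confined so that the radius of gyration stays in the protein-like
#' range around `2.2 L^0.38` A; non-adjacent residues keep at least
#' 3.6 A apart.
#'
#' @param length Number of residues (>= 10).
#' @param seed Integer seed; the same seed gives identical coordinates.
#' @param chain_id Chain identifier for the returned structure.
#' @return A [chain_structure()] with random amino-acid residue names.
#' @export
make_chain <- function(length, seed, chain_id = "A") {
  stopifnot(length >= 10L)
  aa3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
           "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
           "TYR", "VAL")
  with_fixture_seed(seed, {
    rg_target <- 2.2 * length^0.38
    confine <- 1.6 * rg_target
    coords <- matrix(0, length, 3)
    dir <- rand_unit()
    for (i in 2:length) {
      placed <- FALSE
      for (attempt in 1:50) {
        step <- 3.8 + runif(1, -0.05, 0.05)
        prop_dir <- dir + rnorm(3, sd = 0.7)
        # pull back towards the origin when drifting out of the envelope
        r <- sqrt(sum(coords[i - 1, ]^2))
        if (r > confine) prop_dir <- prop_dir - 1.5 * coords[i - 1, ] / r
        prop_dir <- prop_dir / sqrt(sum(prop_dir^2))
        cand <- coords[i - 1, ] + step * prop_dir
        if (i <= 3) { ok <- TRUE } else {
          prev <- coords[1:(i - 2), , drop = FALSE]
          d2 <- rowSums(sweep(prev, 2, cand)^2)
          ok <- all(d2 > 3.6^2)
        }
        if (ok) {
          coords[i, ] <- cand
          dir <- prop_dir
          placed <- TRUE
          break
        }
      }
      if (!placed) {  # rare dead end: step back out along a fresh direction
        dir <- rand_unit()
        coords[i, ] <- coords[i - 1, ] + (3.8 + runif(1, -0.05, 0.05)) * dir
      }
    }
    chain_structure(chain_id, coords,
                    residue_names = sample(aa3, length, replace = TRUE))
  })
}

rand_unit <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

#' Random proper rotation (uniform over SO(3))
#' @return A 3x3 rotation matrix drawn from the current RNG.
#' @export
random_rotation <- function() {
  # quaternion method: uniform on the 3-sphere
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

random_transform <- function(translation_scale = 30) {
  rigid_transform(random_rotation(),
                  rand_unit() * runif(1, 0.5, 1) * translation_scale)
}

#' Fixture specification
#'
#' @param n_chains Number of chains per complex.
#' @param chain_lengths Integer vector of chain lengths (recycled to
#'   `n_chains`).
#' @param noise_sigma Gaussian coordinate noise added to the target
#'   complex, Angstrom. Default 0.5.
#' @param chain_permutation Permutation of `1:n_chains` giving the chain
#'   order of the target complex; default identity.
#' @param decoy If TRUE the target chains are placed with *independent*
#'   per-chain transforms: each chain still matches its partner
#'   individually, but the complex geometry does not.
#' @param seed Integer seed driving all randomness.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_chains, chain_lengths = 40L, noise_sigma = 0.5,
                         chain_permutation = seq_len(n_chains),
                         decoy = FALSE, seed = 1L) {
  stopifnot(n_chains >= 1L, length(chain_permutation) == n_chains,
            all(sort(chain_permutation) == seq_len(n_chains)))
  structure(list(n_chains = as.integer(n_chains),
                 chain_lengths = rep_len(as.integer(chain_lengths), n_chains),
                 noise_sigma = noise_sigma,
                 chain_permutation = as.integer(chain_permutation),
                 decoy = isTRUE(decoy), seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Build a complex pair with planted ground truth
#'
#' Assembles the query complex from independently generated chains
#' placed at random, non-overlapping positions, then builds the target
#' as one global rigid transform of the query with chains renamed (ids
#' following the query's alphabetically), reordered by the spec's
#' permutation, and Gaussian noise added. In decoy mode each target
#' chain gets its own independent transform instead of the shared one,
#' so every chain still matches individually while the complex geometry
#' differs.
#'
#' @param spec A [fixture_spec()].
#' @return List with `query` and `target` ([complex_structure()]s),
#'   `pairing` (data frame `query`/`target` chain ids: the planted
#'   assignment), and `transform` (the planted global
#'   [rigid_transform()], target frame <- query frame is its inverse;
#'   the stored transform maps target coordinates onto the query, as
#'   everywhere in the package).
#' @export
make_complex_pair <- function(spec) {
  n <- spec$n_chains
  qids <- LETTERS[seq_len(n)]
  tids <- LETTERS[n + seq_len(n)]
  base <- lapply(seq_len(n), function(k)
    make_chain(spec$chain_lengths[k], seed = spec$seed * 1000L + k,
               chain_id = qids[k]))
  with_fixture_seed(spec$seed * 1000L + 500L, {
    # place chains without overlap: sequential sphere packing
    rgs <- vapply(base, function(c) {
      x <- sweep(c$ca_coords, 2, colMeans(c$ca_coords))
      sqrt(mean(rowSums(x^2)))
    }, numeric(1))
    centers <- matrix(0, n, 3)
    q_chains <- vector("list", n)
    for (k in seq_len(n)) {
      Rk <- random_rotation()
      if (k > 1) {
        repeat {
          ref <- centers[sample.int(k - 1, 1), ]
          cand <- ref + rand_unit() * (rgs[k] + rgs[sample.int(k - 1, 1)] + 6)
          d <- sqrt(rowSums(sweep(centers[1:(k - 1), , drop = FALSE], 2, cand)^2))
          if (all(d > 0.8 * (rgs[1:(k - 1)] + rgs[k]))) break
        }
        centers[k, ] <- cand
      }
      xc <- sweep(base[[k]]$ca_coords, 2, colMeans(base[[k]]$ca_coords))
      coords <- sweep(xc %*% t(Rk), 2, centers[k, ], "+")
      q_chains[[k]] <- chain_structure(qids[k], coords,
                                       base[[k]]$residue_names,
                                       base[[k]]$residue_numbers)
    }
    G <- random_transform(translation_scale = 40)
    t_chains <- vector("list", n)
    for (j in seq_len(n)) {
      k <- spec$chain_permutation[j]  # target position j holds query chain k
      Gk <- if (spec$decoy) random_transform(translation_scale = 40) else G
      coords <- apply_transform(Gk, q_chains[[k]]$ca_coords)
      if (spec$noise_sigma > 0)
        coords <- coords + matrix(rnorm(length(coords), sd = spec$noise_sigma),
                                  ncol = 3)
      t_chains[[j]] <- chain_structure(tids[j], coords,
                                       q_chains[[k]]$residue_names,
                                       q_chains[[k]]$residue_numbers)
    }
    pairing <- data.frame(query = qids[spec$chain_permutation],
                          target = tids, stringsAsFactors = FALSE)
    pairing <- pairing[order(pairing$query), , drop = FALSE]
    rownames(pairing) <- NULL
    list(query = complex_structure(sprintf("fixQ%d", spec$seed), q_chains),
         target = complex_structure(sprintf("fixT%d", spec$seed), t_chains),
         pairing = pairing,
         transform = invert_transform(G),
         spec = spec)
  })
}

#' Random fixture pair with drawn chain counts and lengths
#'
#' Convenience wrapper: draws the number of chains (2-4 by default),
#' chain lengths (30-60 residues) and a random chain permutation from
#' the seed, then calls [make_complex_pair()].
#'
#' @param seed Integer seed.
#' @param n_chains Number of chains; drawn from `2:4` when NULL.
#' @param noise_sigma Coordinate noise, Angstrom. Default 0.5.
#' @param decoy Decoy-geometry variant? Default FALSE.
#' @return As [make_complex_pair()].
#' @export
random_fixture_pair <- function(seed, n_chains = NULL, noise_sigma = 0.5,
                                decoy = FALSE) {
  params <- with_fixture_seed(seed * 7L + 3L, {
    n <- if (is.null(n_chains)) sample(2:4, 1) else n_chains
    list(n = n,
         lengths = sample(30:60, n, replace = TRUE),
         perm = sample(n))
  })
  make_complex_pair(fixture_spec(params$n, params$lengths,
                                 noise_sigma = noise_sigma,
                                 chain_permutation = params$perm,
                                 decoy = decoy, seed = seed))
}

#' Write a fixture set to disk
#'
#' Writes the query and target of one or more fixture pairs as PDB
#' files plus a `truth.json` with the planted pairing and global
#' transform of each pair.
#'
#' @param dir Output directory (created if missing).
#' @param seeds Integer vector of seeds, one fixture pair per seed.
#' @param noise_sigma,decoy Passed to [random_fixture_pair()].
#' @return Invisibly, the truth list.
#' @export
write_fixture_set <- function(dir, seeds = 1:5, noise_sigma = 0.5,
                              decoy = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- list()
  for (s in seeds) {
    fx <- random_fixture_pair(s, noise_sigma = noise_sigma, decoy = decoy)
    write_pdb(fx$query, file.path(dir, paste0(fx$query$complex_id, ".pdb")))
    write_pdb(fx$target, file.path(dir, paste0(fx$target$complex_id, ".pdb")))
    truth[[as.character(s)]] <- list(
      query = fx$query$complex_id, target = fx$target$complex_id,
      pairing = fx$pairing,
      rotation = fx$transform$rotation,
      translation = fx$transform$translation)
  }
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(truth)
}
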