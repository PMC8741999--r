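#' @name synthetic
#' @title Seeded generators for every pipeline input
#'
#' @description
#' All stages of the pipeline are testable offline: these generators
#' produce annotated variant cohorts with spiked causal alleles and a
#' truth table, pedigrees consistent (or not) with the planned
#' inheritance, two-conformation toy helices with a known mobile segment,
#' compact toy globules for burial calibration, and Gaussian ddG replicate
#' sets. Every generator is a pure function of its spec and seed: the same
#' seed gives byte-identical output, and the caller's RNG state is left
#' untouched.
NULL

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate an ideal helix pair with a mobile segment
#'
#' Builds an ideal alpha-helix backbone (rise 1.5 Angstrom/residue, 100
#' degrees/residue twist, atoms N, CA, C, O plus a CB pseudo-side-chain;
#' glycine-free, but side chains are single CB atoms so geometry code
#' must not assume full side chains). The second conformation applies the
#' hinge rotation locally: residues inside `hinge_interval` are rotated
#' rigidly about the helix axis by `hinge_angle`, so the flanks stay
#' superposable and the per-residue RMSD signal is confined to the mobile
#' segment, emulating locally motile regions between two conformational
#' states. Gaussian coordinate noise is then added to the second
#' conformation.
#'
#' @param n_residues helix length (default 100).
#' @param hinge_interval integer range `c(start, end)` of the mobile
#'   segment (default 20-30).
#' @param hinge_angle rotation in degrees (default 30).
#' @param noise_sd per-coordinate Gaussian noise, Angstrom (default 0.1).
#' @param seed RNG seed.
#' @return list with `reference` and `mobile` (`structure_model`s) and
#'   the generating parameters.
#' @export
generate_helix_pair <- function(n_residues = 100L, hinge_interval = c(20L, 30L),
                                hinge_angle = 30, noise_sd = 0.1, seed = 1L) {
  stopifnot(hinge_interval[1] >= 1L, hinge_interval[2] <= n_residues,
            n_residues >= (hinge_interval[2] - hinge_interval[1] + 1L) + 10L)
  ref <- ideal_helix(n_residues)
  mob <- ref
  hinge <- mob$resseq >= hinge_interval[1] & mob$resseq <= hinge_interval[2]
  a <- hinge_angle * pi / 180
  rot <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3, byrow = TRUE)
  xyz <- as.matrix(mob[hinge, c("x", "y", "z")]) %*% t(rot)
  mob$x[hinge] <- xyz[, 1]; mob$y[hinge] <- xyz[, 2]; mob$z[hinge] <- xyz[, 3]
  if (noise_sd > 0) {
    n <- nrow(mob)
    noise <- with_seed(seed, matrix(stats::rnorm(3L * n, 0, noise_sd), n, 3L))
    mob$x <- mob$x + noise[, 1]; mob$y <- mob$y + noise[, 2]; mob$z <- mob$z + noise[, 3]
  }
  list(reference = structure_model(ref, id = "helix_ref"),
       mobile = structure_model(mob, id = "helix_mobile"),
       hinge_interval = hinge_interval, hinge_angle = hinge_angle,
       noise_sd = noise_sd, seed = seed)
}

# ideal helix atom table along z; per-atom radius/phase/rise offsets are
# approximate but give distinct, chemically sensible backbone positions
ideal_helix <- function(n_residues, chain = "A") {
  geom <- list(N  = c(r = 1.60, dphi = -0.55, dz = -0.60),
               CA = c(r = 2.30, dphi = 0.00, dz = 0.00),
               C  = c(r = 1.70, dphi = 0.45, dz = 0.60),
               O  = c(r = 2.00, dphi = 0.55, dz = 1.40),
               CB = c(r = 3.30, dphi = -0.15, dz = -0.10))
  rows <- list()
  serial <- 0L
  for (i in seq_len(n_residues)) {
    phi <- i * 100 * pi / 180
    z <- i * 1.5
    for (an in names(geom)) {
      g <- geom[[an]]
      serial <- serial + 1L
      rows[[serial]] <- data.frame(
        serial = serial, atom_name = an, resname = "ALA", chain = chain,
        resseq = i, icode = "",
        x = g["r"] * cos(phi + g["dphi"]),
        y = g["r"] * sin(phi + g["dphi"]),
        z = z + g["dz"],
        occupancy = 1, element = substr(an, 1, 1), het = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a compact toy globule with a peripheral residue
#'
#' Packs `n_residues` five-atom residues (N, CA, C, O, CB) at random
#' positions inside a sphere, plus one extra residue appended at the
#' periphery. Residue 1 sits at the center. Used to calibrate and test
#' the burial proxy: the core residue's neighbor count strictly exceeds
#' the peripheral one's.
#'
#' @param n_residues residues in the globule body (default 20).
#' @param radius globule radius, Angstrom (default 7).
#' @param seed RNG seed.
#' @return list with `model` (`structure_model`), `core` and `periphery`
#'   residue selectors.
#' @export
generate_globule <- function(n_residues = 20L, radius = 7, seed = 1L) {
  centers <- with_seed(seed, {
    pts <- matrix(stats::rnorm(3L * n_residues), ncol = 3L)
    pts <- pts / sqrt(rowSums(pts^2)) * radius * stats::runif(n_residues)^(1 / 3)
    pts[1, ] <- 0  # core residue at the center
    rbind(pts, c(radius + 8, 0, 0))  # peripheral residue
  })
  offs <- rbind(N = c(-0.6, 0, 0), CA = c(0, 0, 0), C = c(0.6, 0, 0),
                O = c(0.6, 0.6, 0), CB = c(0, -0.7, 0.7))
  rows <- list(); serial <- 0L
  for (i in seq_len(nrow(centers))) {
    for (an in rownames(offs)) {
      serial <- serial + 1L
      rows[[serial]] <- data.frame(
        serial = serial, atom_name = an, resname = "ALA", chain = "A",
        resseq = i, icode = "",
        x = centers[i, 1] + offs[an, 1], y = centers[i, 2] + offs[an, 2],
        z = centers[i, 3] + offs[an, 3],
        occupancy = 1, element = substr(an, 1, 1), het = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  model <- structure_model(do.call(rbind, rows), id = "globule")
  list(model = model,
       core = list(chain = "A", resseq = 1L),
       periphery = list(chain = "A", resseq = nrow(centers)))
}

#' Generate Gaussian ddG replicate sets
#'
#' Draws `n_replicas` Normal(mu, sd) replicas per variant, emulating the
#' five-replica force-field protocol.
#'
#' @param truth data frame with columns `label`, `mu`, `sd`.
#' @param n_replicas replicas per variant (default 5).
#' @param seed RNG seed.
#' @return a `ddg_table` (named list of [ddg_replicate_set()]).
#' @export
generate_ddg_sets <- function(truth, n_replicas = 5L, seed = 1L) {
  stopifnot(all(c("label", "mu", "sd") %in% names(truth)), all(truth$sd >= 0))
  out <- with_seed(seed, {
    sets <- list()
    for (i in seq_len(nrow(truth))) {
      sets[[truth$label[i]]] <- ddg_replicate_set(
        truth$label[i],
        replicas = stats::rnorm(n_replicas, truth$mu[i], truth$sd[i]))
    }
    sets
  })
  class(out) <- "ddg_table"
  out
}

#' Cohort generation spec
#'
#' Study conditions for the synthetic cohort: 32 probands, half carrying
#' a spiked causal plan (the cohort-level findings rate the pipeline is
#' expected to recover is controlled by `spike_fraction`, default 0.625),
#' an autosomal-recessive fraction among spiked cases, rare-variant
#' background noise with Beta(0.2, 5) allele frequencies (most background
#' variants rare, a controlled tail violating the MAF ceilings), and
#' synonymous/intronic decoy consequences exercising the filters.
#'
#' @param n_patients cohort size (default 32).
#' @param panel a [gene_panel()]; default the shipped stand-in panel.
#' @param fraction_ar fraction of spiked cases with recessive plans.
#' @param spike_fraction fraction of patients receiving a causal spike.
#' @param spike_tiers planned tiers sampled for spikes.
#' @param background_per_patient background variants per patient.
#' @param maf_beta Beta distribution parameters for background MAFs.
#' @param seed RNG seed.
#' @export
cohort_spec <- function(n_patients = 32L, panel = NULL, fraction_ar = 0.5,
                        spike_fraction = 0.625,
                        spike_tiers = c("Pathogenic", "LikelyPathogenic"),
                        background_per_patient = 8L,
                        maf_beta = c(0.2, 5), seed = 1L) {
  if (is.null(panel)) panel <- load_fixture("panel")
  stopifnot(inherits(panel, "gene_panel"), fraction_ar >= 0, fraction_ar <= 1)
  structure(list(n_patients = n_patients, panel = panel,
                 fraction_ar = fraction_ar, spike_fraction = spike_fraction,
                 spike_tiers = spike_tiers,
                 background_per_patient = background_per_patient,
                 maf_beta = maf_beta, seed = seed),
            class = "cohort_spec")
}

# evidence-code plans whose combined tier is verified at generation time
SPIKE_CRITERIA <- list(
  Pathogenic = "PVS1, PM2, PM3",
  LikelyPathogenic = "PM2, PM3, PP3, PP4"
)

#' Generate a synthetic annotated cohort with spiked causal variants
#'
#' Per patient: an inheritance model, optionally a spiked causal plan
#' (recessive plans are biallelic: a homozygous variant or an in-trans
#' heterozygous pair in one gene), and Beta-distributed rare background
#' variants with decoy consequence classes. Spiked variants are
#' constructed to survive all three filters (in-panel gene, kept
#' consequence, MAF under the ceiling) and their criteria strings are
#' verified at generation to combine to the planned tier. Pedigrees
#' consistent with each spiked plan are emitted, and a truth table
#' records every spike.
#'
#' @param spec a [cohort_spec()].
#' @return list with `variants` (one `variant_table` for the cohort),
#'   `inheritance` (named by patient), `pedigrees` (per patient: named
#'   list by cdna), and `truth` (data frame of spikes).
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    panel_genes <- spec$panel$genes
    bg_genes <- c(sample(panel_genes, min(20L, length(panel_genes))),
                  sprintf("OFFPANEL%02d", 1:20))
    decoys <- c("missense", "synonymous", "intronic", "missense", "nonsense",
                "synonymous", "splice_site", "other")
    rows <- list(); peds <- list(); truth <- list(); inh <- character(spec$n_patients)
    vid <- 0L
    new_cdna <- function() { vid <<- vid + 1L
      sprintf("c.%d%s>%s", 100L + vid * 7L, sample(c("A", "C", "G", "T"), 1),
              sample(c("A", "C", "G", "T"), 1)) }
    for (pi in seq_len(spec$n_patients)) {
      pid <- sprintf("S%02d", pi)
      spiked <- stats::runif(1) < spec$spike_fraction
      ar <- stats::runif(1) < spec$fraction_ar
      inh[pi] <- if (ar) "autosomal_recessive" else "autosomal_dominant"
      peds[[pid]] <- list()
      if (spiked) {
        tier <- sample(spec$spike_tiers, 1L)
        gene <- sample(panel_genes, 1L)
        if (ar) {
          hom <- stats::runif(1) < 0.5
          n_alleles <- if (hom) 1L else 2L
          segs <- c("Maternal", "Paternal")
          for (k in seq_len(n_alleles)) {
            cd <- new_cdna()
            rows[[length(rows) + 1L]] <- spike_row(pid, gene, cd, tier,
              zygosity = if (hom) "hom" else "het",
              segregation = if (hom) "Segregation confirmed" else segs[k])
            peds[[pid]][[cd]] <- pedigree(
              c("p", "m", "f"), c("proband", "mother", "father"),
              c(TRUE, FALSE, FALSE),
              c("biallelic", "het", "het"))
            truth[[length(truth) + 1L]] <- data.frame(
              patient_id = pid, gene = gene, cdna = cd, tier_planned = tier,
              zygosity = if (hom) "hom" else "het", stringsAsFactors = FALSE)
          }
        } else {
          cd <- new_cdna()
          rows[[length(rows) + 1L]] <- spike_row(pid, gene, cd, tier,
            zygosity = "het", segregation = "Maternal")
          peds[[pid]][[cd]] <- pedigree(
            c("p", "m", "f"), c("proband", "mother", "father"),
            c(TRUE, TRUE, FALSE), c("het", "het", "ref"))
          truth[[length(truth) + 1L]] <- data.frame(
            patient_id = pid, gene = gene, cdna = cd, tier_planned = tier,
            zygosity = "het", stringsAsFactors = FALSE)
        }
      }
      for (b in seq_len(spec$background_per_patient)) {
        af <- stats::rbeta(1, spec$maf_beta[1], spec$maf_beta[2])
        rows[[length(rows) + 1L]] <- data.frame(
          patient_id = pid, gene = sample(bg_genes, 1L), transcript = "NM_000000.0",
          cdna = new_cdna(), protein = NA_character_,
          consequence = sample(decoys, 1L), zygosity = "het",
          dbsnp = NA_character_, af_global = af,
          segregation = NA_character_, reference = NA_character_,
          clinvar = NA_character_, criteria = NA_character_,
          spiked = FALSE, tier_planned = NA_character_,
          stringsAsFactors = FALSE)
      }
    }
    variants <- do.call(rbind, rows)
    class(variants) <- c("variant_table", "data.frame")
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(patient_id = character(0), gene = character(0),
                 cdna = character(0), tier_planned = character(0),
                 zygosity = character(0))
    names(inh) <- sprintf("S%02d", seq_len(spec$n_patients))
    list(variants = variants, inheritance = inh, pedigrees = peds, truth = truth)
  })
}

spike_row <- function(pid, gene, cdna, tier, zygosity, segregation) {
  criteria <- SPIKE_CRITERIA[[tier]]
  stopifnot(identical(combine_evidence(criteria), tier))  # verified at generation
  data.frame(patient_id = pid, gene = gene, transcript = "NM_000000.0",
             cdna = cdna, protein = NA_character_, consequence = "missense",
             zygosity = zygosity, dbsnp = NA_character_,
             af_global = 0.0005, segregation = segregation,
             reference = "This work", clinvar = NA_character_,
             criteria = criteria, spiked = TRUE, tier_planned = tier,
             stringsAsFactors = FALSE)
}
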