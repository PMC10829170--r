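# Offline synthetic-data generator: scaffold-structured molecule libraries
# (ring-system templates decorated with small substituents) and synthetic
# DDI pair tables whose side-effect label is a deterministic function of the
# pair's scaffold combination, with a geometric class-imbalance profile and
# optional label noise. This gives every pipeline stage a dataset in which
# scaffold-clustered representations are genuinely informative.

FIXTURE_TEMPLATES <- c(
  benzene         = "%sc1ccc(%s)cc1",
  pyridine        = "%sc1ccc(%s)nc1",
  naphthalene     = "%sc1ccc2ccc(%s)cc2c1",
  cyclohexane     = "%sC1CCC(%s)CC1",
  piperidine      = "%sC1CCC(%s)CN1",
  thiophene       = "%sc1ccc(%s)s1",
  furan           = "%sc1ccc(%s)o1",
  pyrrole         = "%sc1ccc(%s)[nH]1",
  tetrahydropyran = "%sC1CCC(%s)OC1",
  pyrimidine      = "%sc1cnc(%s)nc1"
)

FIXTURE_SUBSTITUENTS <- c("C", "CC", "N", "O", "Cl", "F", "OC", "CCC")

#' Synthetic-fixture configuration
#'
#' @param n_scaffold_families number of scaffold templates used (<= 10).
#' @param per_family distinct molecules generated per family.
#' @param n_classes number of side-effect classes (>= 2).
#' @param imbalance_decay geometric decay of class frequencies in (0, 1\];
#'   class k has frequency proportional to `imbalance_decay^k`.
#' @param label_noise probability that a pair's label is flipped to a
#'   uniformly chosen other class.
#' @param n_pairs number of DDI pairs to sample.
#' @param seed integer seed; both generators are deterministic under it.
#' @return list of class `fixture_config`.
#' @export
fixture_config <- function(n_scaffold_families = 8L, per_family = 25L,
                           n_classes = 6L, imbalance_decay = 0.5,
                           label_noise = 0.02, n_pairs = 2000L, seed = 0L) {
  if (n_scaffold_families < 1L || n_scaffold_families > length(FIXTURE_TEMPLATES))
    config_error(sprintf("n_scaffold_families must be in 1..%d",
                         length(FIXTURE_TEMPLATES)))
  if (imbalance_decay <= 0 || imbalance_decay > 1)
    config_error("imbalance_decay must be in (0, 1]")
  if (label_noise < 0 || label_noise >= 1)
    config_error("label_noise must be in [0, 1)")
  structure(list(n_scaffold_families = as.integer(n_scaffold_families),
                 per_family = as.integer(per_family),
                 n_classes = as.integer(n_classes),
                 imbalance_decay = imbalance_decay,
                 label_noise = label_noise, n_pairs = as.integer(n_pairs),
                 seed = as.integer(seed)),
            class = "fixture_config")
}

#' Generate a scaffold-structured molecule library
#'
#' For each scaffold template (benzene, pyridine, naphthalene, cyclohexane,
#' piperidine, ...) all pairwise decorations with a fixed substituent list
#' are enumerated, canonicalized and de-duplicated; `per_family` distinct
#' molecules are drawn per family with a seeded shuffle. Every emitted
#' molecule's Murcko scaffold equals its template's scaffold.
#'
#' @param config a [fixture_config()].
#' @return molecule table (data.frame `id`, `smiles_canonical`, `scaffold`).
#' @export
generate_molecule_library <- function(config = fixture_config()) {
  if (config$per_family < 1L) config_error("per_family must be >= 1")
  fams <- FIXTURE_TEMPLATES[seq_len(config$n_scaffold_families)]
  out <- list()
  for (f in seq_along(fams)) {
    tpl <- fams[[f]]
    combos <- expand.grid(a = FIXTURE_SUBSTITUENTS, b = FIXTURE_SUBSTITUENTS,
                          stringsAsFactors = FALSE)
    smis <- sprintf(tpl, combos$a, combos$b)
    canon <- unique(canonicalize_batch(smis))
    canon <- canon[!is.na(canon)]
    if (length(canon) < config$per_family)
      config_error(sprintf(
        "family %s yields only %d distinct molecules (< per_family = %d)",
        names(fams)[f], length(canon), config$per_family))
    sel <- with_seed(derive_seed(config$seed, "family", f),
                     sample(canon, config$per_family))
    scaffold <- murcko_scaffold(sel[1])
    out[[f]] <- data.frame(
      id = sprintf("%s_%02d", names(fams)[f], seq_along(sel)),
      smiles_canonical = sel, scaffold = scaffold,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Generate a synthetic DDI pair table
#'
#' Every unordered scaffold-family combination is assigned one side-effect
#' class through a seeded lookup table (each class receives a contiguous
#' share of combinations so that all classes are realizable); pairs are then
#' sampled so that class frequencies follow the geometric imbalance profile
#' `imbalance_decay^k`, the two drugs are drawn uniformly from the families
#' of the chosen combination, and the label is flipped to a random other
#' class with probability `label_noise`.
#'
#' @param library a molecule table from [generate_molecule_library()].
#' @param config a [fixture_config()].
#' @return data.frame `drug1_smiles`, `drug2_smiles`, `label` (integer
#'   0..C-1), with the scaffold-combination lookup in
#'   `attr(, "combo_classes")`.
#' @export
generate_ddi_dataset <- function(library, config = fixture_config()) {
  C <- config$n_classes
  if (C < 2L) config_error("n_classes must be >= 2")
  fams <- unique(library$scaffold)
  nf <- length(fams)
  combos <- if (nf >= 2L) {
    cbind(utils::combn(nf, 2L), rbind(seq_len(nf), seq_len(nf)))  # + (i, i)
  } else {
    matrix(1L, 2, 1)
  }
  n_combo <- ncol(combos)
  if (C > n_combo)
    config_error(sprintf("n_classes = %d exceeds %d scaffold combinations",
                         C, n_combo))
  p_class <- config$imbalance_decay^(seq_len(C) - 1L)
  p_class <- p_class / sum(p_class)
  with_seed(derive_seed(config$seed, "ddi"), {
    # seeded lookup: shuffle combos, give each class a contiguous share
    ord <- sample.int(n_combo)
    share <- pmax(1L, round(p_class * n_combo))
    while (sum(share) > n_combo) share[which.max(share)] <- share[which.max(share)] - 1L
    while (sum(share) < n_combo) share[which.min(share)] <- share[which.min(share)] + 1L
    combo_class <- integer(n_combo)
    combo_class[ord] <- rep(seq_len(C) - 1L, times = share)
    by_class <- split(seq_len(n_combo), combo_class)
    mols_by_fam <- split(library$smiles_canonical, match(library$scaffold, fams))
    # sample pairs: class ~ geometric profile, then a combo of that class,
    # then one molecule from each family of the combo
    cls <- sample.int(C, config$n_pairs, replace = TRUE, prob = p_class) - 1L
    d1 <- character(config$n_pairs); d2 <- character(config$n_pairs)
    for (i in seq_len(config$n_pairs)) {
      cc <- by_class[[as.character(cls[i])]]
      co <- combos[, cc[sample.int(length(cc), 1L)]]
      m1 <- mols_by_fam[[co[1]]]; m2 <- mols_by_fam[[co[2]]]
      d1[i] <- m1[sample.int(length(m1), 1L)]
      d2[i] <- m2[sample.int(length(m2), 1L)]
      if (d1[i] == d2[i] && length(m2) > 1L) {
        d2[i] <- sample(setdiff(m2, d1[i]), 1L)
      }
    }
    noisy <- config$label_noise > 0 &
      stats::runif(config$n_pairs) < config$label_noise
    if (any(noisy)) {
      cls[noisy] <- vapply(cls[noisy], function(y) {
        sample(setdiff(seq_len(C) - 1L, y), 1L)
      }, integer(1))
    }
    out <- data.frame(drug1_smiles = d1, drug2_smiles = d2, label = cls,
                      stringsAsFactors = FALSE)
    lookup <- data.frame(scaffold1 = fams[combos[1, ]],
                         scaffold2 = fams[combos[2, ]], class = combo_class)
    attr(out, "combo_classes") <- lookup
    attr(out, "label_levels") <- as.character(seq_len(C) - 1L)
    out
  })
}

#' Write fixture files to a directory
#'
#' Emits `molecules.csv` (id, smiles, scaffold) and `ddi_pairs.csv`
#' (drug1_smiles, drug2_smiles, label) in the formats the loaders read.
#'
#' @param dir output directory (created if missing).
#' @param config a [fixture_config()].
#' @return the directory, invisibly.
#' @export
write_fixtures <- function(dir, config = fixture_config()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lib <- generate_molecule_library(config)
  pairs <- generate_ddi_dataset(lib, config)
  utils::write.csv(data.frame(id = lib$id, smiles = lib$smiles_canonical,
                              scaffold = lib$scaffold),
                   file.path(dir, "molecules.csv"), row.names = FALSE)
  utils::write.csv(pairs, file.path(dir, "ddi_pairs.csv"), row.names = FALSE)
  invisible(dir)
}
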