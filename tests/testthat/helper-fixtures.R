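# shared fixtures, built in code

# structure from an explicit residue list: Calphas on a straight line at
# 3.8 A spacing along x (residue i at x = (i-1) * 3.8), full heavy-atom
# complement per residue at idealized offsets
line_structure <- function(residues, chain = "A", sourceId = "LINE",
                           spacing = 3.8) {
  aa_atoms <- pocketec:::AA_HEAVY_ATOMS
  tabs <- lapply(seq_along(residues), function(i) {
    res <- residues[i]
    nm <- aa_atoms[[res]]
    ca <- c((i - 1) * spacing, 0, 0)
    xyz <- matrix(NA_real_, length(nm), 3L, dimnames = list(nm, NULL))
    xyz["N", ] <- ca + c(-1, -1, 0)
    xyz["CA", ] <- ca
    xyz["C", ] <- ca + c(1, -1, 0)
    xyz["O", ] <- ca + c(1, -1.9, 0)
    side <- setdiff(nm, c("N", "CA", "C", "O"))
    for (k in seq_along(side))
      xyz[side[k], ] <- ca + c(0, 0, 0.9 + 0.75 * k)
    data.frame(atom_name = nm, element = substr(nm, 1, 1),
               residue_name = res, chain_id = chain, residue_seq = i,
               insert = "", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               occupancy = 1, is_hydrogen = FALSE,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, tabs)
  rownames(tab) <- NULL
  methods::new("ProteinStructure", atoms = tab, sourceId = sourceId,
               ecLabel = NA_character_, depositionDate = as.Date(NA))
}

# the 5-residue toy with Calphas at x = 0, 3.8, 7.6, 11.4, 15.2
t5_structure <- function() line_structure(rep("GLY", 5), sourceId = "T5")

origin_site <- function() bindingSite(c(0, 0, 0))

# PDB text fixture: GLY-ALA-SER-LYS-TRP protein chain (38 heavy atoms)
# + 10 waters + a short DNA chain
fixture_pdb_text <- function() {
  s <- line_structure(c("GLY", "ALA", "SER", "LYS", "TRP"))
  lines <- writeStructure(s)
  lines <- setdiff(lines, "END")
  wat <- vapply(1:10, function(i) sprintf(
    "HETATM%5d  O   HOH W%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           O",
    900 + i, i, 30 + i, 5, 5, 1, 0), character(1))
  dna <- vapply(1:4, function(i) sprintf(
    "ATOM  %5d  P    D%s D%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           P",
    950 + i, c("A", "C", "G", "T")[i], i, 40 + i, 8, 8, 1, 0), character(1))
  c(lines, wat, dna, "END")
}

# random rigid motion applied to a ProteinGraph
rotate_graph <- function(g, R = NULL, t = NULL) {
  if (is.null(R)) R <- pocketec:::random_rotation()
  if (is.null(t)) t <- stats::rnorm(3, sd = 10)
  methods::initialize(g, positions = g@positions %*% R +
    matrix(t, nrow(g@positions), 3, byrow = TRUE))
}

# small random geometric graph for network tests
random_graph <- function(n = 8, seed = 1, nTypes = 21, radius = 6,
                         maxNeighbors = 6, label = 1L) {
  set.seed(seed)
  repeat {
    pos <- matrix(stats::runif(n * 3, 0, 6), n, 3)
    if (min(stats::dist(pos)) > 0.5) break
  }
  types <- sample.int(nTypes, n, replace = TRUE)
  dm <- as.matrix(stats::dist(pos))
  el <- list()
  for (i in seq_len(n)) {
    cand <- setdiff(which(dm[, i] <= radius), i)
    cand <- cand[order(dm[cand, i], cand)]
    cand <- cand[seq_len(min(maxNeighbors, length(cand)))]
    if (length(cand)) el[[i]] <- cbind(cand, i)
  }
  edges <- do.call(rbind, el)
  storage.mode(edges) <- "integer"
  methods::new("ProteinGraph", positions = pos, types = as.integer(types),
               edges = edges, label = label, resolution = "residue",
               neighborRadius = radius,
               provenance = list(structure_id = paste0("RG", seed),
                                 site_rank = 1L),
               schemeVersion = "test")
}

tiny_model <- function(architecture = "distances", nClasses = 3,
                       seed = 1, ...) {
  defaults <- if (architecture == "distances")
    list(embeddingDim = 8L, nInteractions = 2L, nGaussians = 6L, cutoff = 6)
  else
    list(embeddingDim = 8L, nBlocks = 2L, nGaussians = 6L,
         basisEmbedding = 4L, interactionEmbedding = 6L,
         outputEmbedding = 8L, numSpherical = 3L, numRadial = 2L,
         cutoff = 6)
  args <- c(list(architecture = architecture,
                 classVocab = paste0("c", seq_len(nClasses)),
                 seed = seed), defaults)
  over <- list(...)
  args[names(over)] <- over
  do.call(graphClassifier, args)
}
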