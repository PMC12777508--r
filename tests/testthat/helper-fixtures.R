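# shared fixtures: the two telomeric-repeat 6-mers and their annotations
rna1 <- function() rna_strand("UAGGGU")
rna2 <- function() rna_strand("UUAGGG")

annot1 <- function() tetrad_annotation(6, 3:6, c("G", "G", "G", "U"))
annot2 <- function() tetrad_annotation(6, 4:6, c("G", "G", "G"))

model1 <- function() quadruplex_model(c("G", "G", "G", "U"), 1:3)
model2 <- function() quadruplex_model(c("G", "G", "G"), 1:2)

# published monoisotopic m/z grid for the tetrameric quadruplex ions,
# (4 RNA + x Cat+ - h H+)^n- with x = 1..3 and n = 4..8
published_mz_grid <- function() {
  k <- tibble::tribble(
    ~x, ~n, ~h, ~mz,
    3L, 4L, 7L, 1941.749,  3L, 5L, 8L, 1553.198,  3L, 6L, 9L, 1294.164,
    3L, 7L, 10L, 1109.139, 3L, 8L, 11L, 970.371,
    2L, 4L, 6L, 1932.260,  2L, 5L, 7L, 1545.607,  2L, 6L, 8L, 1287.838,
    2L, 7L, 9L, 1103.717,  2L, 8L, 10L, 965.627,
    1L, 4L, 5L, 1922.771,  1L, 5L, 6L, 1538.016,  1L, 6L, 7L, 1281.512,
    1L, 7L, 8L, 1098.295,  1L, 8L, 9L, 960.882
  )
  nh4 <- tibble::tribble(
    ~x, ~n, ~h, ~mz,
    3L, 4L, 7L, 1926.052,  3L, 5L, 8L, 1540.640,  3L, 6L, 9L, 1283.699,
    3L, 7L, 10L, 1100.170, 3L, 8L, 11L, 962.523,
    2L, 4L, 6L, 1921.796,  2L, 5L, 7L, 1537.235,  2L, 6L, 8L, 1280.861,
    2L, 7L, 9L, 1097.737,  2L, 8L, 10L, 960.394,
    1L, 4L, 5L, 1917.539,  1L, 5L, 6L, 1533.830,  1L, 6L, 7L, 1278.024,
    1L, 7L, 8L, 1095.305,  1L, 8L, 9L, 958.266
  )
  dplyr::bind_rows(
    dplyr::mutate(k, cation = "K"),
    dplyr::mutate(nh4, cation = "NH4")
  )
}

# noiseless logistic breakdown trajectory as a breakdown_curve
logistic_curve <- function(p0 = 100, e_mid = 150, w = 10,
                           energies = seq(50, 300, by = 10)) {
  q <- p0 / (1 + exp((energies - e_mid) / w))
  as_breakdown_curve(tibble::tibble(
    energy = rep(energies, 2),
    species = rep(c("Q", "M"), each = length(energies)),
    pct = c(q, 100 - q)
  ))
}
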