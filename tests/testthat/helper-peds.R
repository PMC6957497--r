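# toy pedigrees used across tests, built from .fam-dialect text

ped_from <- function(...) read_pedigree(text = c(...))[[1]]

ped_trio <- function() {
  ped_from("t F 0 0 1 -9", "t M 0 0 2 -9", "t C F M 1 -9")
}

# parent-child pair (only one recorded parent)
ped_pair <- function() {
  ped_from("p P 0 0 1 -9", "p C P 0 1 -9")
}

ped_quad <- function() {
  ped_from("q A 0 0 1 -9", "q B 0 0 2 -9", "q C A B 1 -9", "q D A B 2 -9")
}

# mother + two children, father absent
ped_one_parent3 <- function() {
  ped_from("o M 0 0 2 -9", "o K1 0 M 1 -9", "o K2 0 M 2 -9")
}

ped_3gen5 <- function() {
  ped_from("g G1 0 0 1 -9", "g G2 0 0 2 -9", "g P1 G1 G2 1 -9",
           "g S1 0 0 2 -9", "g K1 P1 S1 1 -9")
}

ped_3gen6 <- function() {
  ped_from("g G1 0 0 1 -9", "g G2 0 0 2 -9", "g P1 G1 G2 1 -9",
           "g S1 0 0 2 -9", "g K1 P1 S1 1 -9", "g K2 P1 S1 2 -9")
}

# three generations, two unlinked parental sibships once grandparents go
ped_8split <- function() {
  ped_from(
    "s G1 0 0 1 -9", "s G2 0 0 2 -9",
    "s P1 G1 G2 1 -9", "s P2 G1 G2 2 -9",
    "s S1 0 0 2 -9", "s S2 0 0 1 -9",
    "s K1 P1 S1 1 -9", "s K2 S2 P2 2 -9"
  )
}

# 2 grandparents, 2 of their children (one married-in spouse), 3 grandkids
ped_8nf <- function() {
  ped_from(
    "n G1 0 0 1 -9", "n G2 0 0 2 -9",
    "n P1 G1 G2 1 -9", "n P2 G1 G2 2 -9", "n S1 0 0 2 -9",
    "n K1 P1 S1 1 -9", "n K2 P1 S1 2 -9", "n K3 P1 S1 1 -9"
  )
}

small_peds <- function() {
  list(trio = ped_trio(), pair = ped_pair(), quad = ped_quad(),
       one_parent = ped_one_parent3(), gen5 = ped_3gen5(),
       gen6 = ped_3gen6())
}
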