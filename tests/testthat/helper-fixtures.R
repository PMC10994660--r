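# Small networks, built in code, used across the simulator and fitting
# tests. All have <= 8 reactions and <= 6 carbons so the exhaustive
# isotopomer oracle is cheap.

met <- function(carbons, role = "internal", pathway = NA)
  list(carbons = carbons, role = role, pathway = pathway)

# linear 3-carbon chain: Ain -> A -> B -> C -> (sink); 1 dof
toy_chain <- function() build_network(list(
  name = "toy_chain",
  metabolites = list(Ain = met(3, "input"), A = met(3), B = met(3),
                     C = met(3)),
  reactions = list(
    list(name = "uptake", equation = "Ain[abc] -> A[abc]"),
    list(name = "a2b", equation = "A[abc] -> B[abc]"),
    list(name = "b2c", equation = "B[abc] -> C[abc]"),
    list(name = "c_eff", equation = "C[abc] ->")),
  inputs = list(Ain = "tracer")))

# cleavage and recondensation of a 4-carbon input
toy_cleave <- function() build_network(list(
  name = "toy_cleave",
  metabolites = list(Din = met(4, "input"), D = met(4), E = met(2),
                     F = met(2), G = met(4)),
  reactions = list(
    list(name = "uptake", equation = "Din[abcd] -> D[abcd]"),
    list(name = "cleave", equation = "D[abcd] -> E[ab] + F[cd]"),
    list(name = "cond", equation = "E[ab] + F[cd] -> G[cdab]"),
    list(name = "g_eff", equation = "G[abcd] ->")),
  inputs = list(Din = "tracer")))

# genuine label recycle: acetyl-unit condensation onto a regenerated carrier;
# the split scrambles old-carrier and fresh carbons so the cycle both mixes
# and turns over (every carbon eventually exits through W)
toy_cycle <- function() build_network(list(
  name = "toy_cycle",
  metabolites = list(Ac = met(2, "input"), X = met(4), Y = met(2),
                     W = met(2)),
  reactions = list(
    list(name = "cond", equation = "Ac[ab] + Y[cd] -> X[cdab]"),
    list(name = "split", equations = list(
      list(map = "X[abcd] -> Y[cd] + W[ab]", weight = 0.5),
      list(map = "X[abcd] -> Y[ad] + W[cb]", weight = 0.5))),
    list(name = "w_eff", equation = "W[ab] ->")),
  inputs = list(Ac = "tracer")))

# molecular symmetry: equal-weight alternative atom maps, then a split that
# exposes the positional scrambling
toy_sym <- function() build_network(list(
  name = "toy_sym",
  metabolites = list(Sin = met(2, "input"), S = met(2), T = met(2),
                     U = met(1), V = met(1)),
  reactions = list(
    list(name = "uptake", equation = "Sin[ab] -> S[ab]"),
    list(name = "scramble", equations = list(
      list(map = "S[ab] -> T[ab]", weight = 0.5),
      list(map = "S[ab] -> T[ba]", weight = 0.5))),
    list(name = "split", equation = "T[ab] -> U[a] + V[b]"),
    list(name = "u_eff", equation = "U[a] ->"),
    list(name = "v_eff", equation = "V[a] ->")),
  inputs = list(Sin = "tracer")))

# hexose cleaved into two trioses funneled into one lactate-like pool
toy_glycolysis <- function() build_network(list(
  name = "toy_glycolysis",
  metabolites = list(Hin = met(6, "input"), H = met(6), T = met(3),
                     U = met(3), L = met(3)),
  reactions = list(
    list(name = "uptake", equation = "Hin[abcdef] -> H[abcdef]"),
    list(name = "cleave", equation = "H[abcdef] -> T[cba] + U[def]"),
    list(name = "u2t", equation = "U[abc] -> T[abc]"),
    list(name = "t2l", equation = "T[abc] -> L[abc]"),
    list(name = "l_eff", equation = "L[abc] ->")),
  inputs = list(Hin = "tracer")))

toy_networks <- function() list(
  chain = list(model = toy_chain(),
               fluxes = c(uptake = 10, a2b = 10, b2c = 10, c_eff = 10)),
  cleave = list(model = toy_cleave(),
                fluxes = c(uptake = 8, cleave = 8, cond = 8, g_eff = 8)),
  cycle = list(model = toy_cycle(),
               fluxes = c(cond = 10, split = 10, w_eff = 10)),
  sym = list(model = toy_sym(),
             fluxes = c(uptake = 4, scramble = 4, split = 4, u_eff = 4,
                        v_eff = 4)),
  glycolysis = list(model = toy_glycolysis(),
                    fluxes = c(uptake = 5, cleave = 5, u2t = 5, t2l = 10,
                               l_eff = 10)))

# half-labeled 2-carbon input: 50% M+0 / 50% M+2
half_labeled2 <- function() c(0.5, 0, 0, 0.5)

# fixed boundary drains of each study condition, as the fit configures them
scenario_fixed <- function(name) {
  sc <- scenario_spec(name)
  c(list(hk = 100, lac_eff = sc$lactate_efflux), sc$fixed_effluxes)
}

max_mdv_diff <- function(a, b)
  max(vapply(names(a), function(n) max(abs(a[[n]] - b[[n]])), 0))
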