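# Idealized deoxyribonucleotide heavy-atom geometry from the standard
# chemical-component dictionary, embedded so synthetic structures need
# no runtime lookup. Each template is re-posed at load time so the
# base best-fit plane is z = 0 with the base centroid at the origin.
NT_TEMPLATES <- list(
  DG = list(
    atom = c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'", "C3'", "O3'", "C2'", "C1'", "N9", "C8", "N7", "C5", "C6", "O6", "N1", "C2", "N2", "N3", "C4"),
    elem = c("P", "O", "O", "O", "C", "C", "O", "C", "O", "C", "C", "N", "C", "N", "C", "C", "O", "N", "C", "N", "N", "C"),
    x = c(-0.818, -1.774, 0.312, -0.126, 0.550, 1.233, 0.253, 1.976, 3.294, 2.026, 0.897, -0.068, -1.172, -1.804, -1.145, -1.361, -2.321, -0.473, 0.593, 1.474, 0.804, -0.027),
    y = c(-0.321, 0.766, 0.224, -0.826, 0.300, -0.113, -0.471, 1.091, 1.218, 0.692, -0.345, 0.111, 0.877, 1.094, 0.482, 0.377, 0.914, -0.327, -0.928, -1.643, -0.839, -0.152),
    z = c(4.935, 4.630, 5.941, 3.572, 3.011, 1.706, 0.705, 1.073, 1.612, -0.421, -0.573, -1.575, -1.341, -2.458, -3.472, -4.866, -5.391, -5.601, -5.003, -5.774, -3.709, -2.917)),
  DA = list(
    atom = c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'", "C3'", "O3'", "C2'", "C1'", "N9", "C8", "N7", "C5", "C6", "N6", "N1", "C2", "N3", "C4"),
    elem = c("P", "O", "O", "O", "C", "C", "O", "C", "O", "C", "C", "N", "C", "N", "C", "C", "N", "N", "C", "N", "C"),
    x = c(0.934, 1.781, -0.204, 0.241, -0.549, -1.239, -0.267, -2.105, -3.409, -2.173, -0.965, -0.078, 0.962, 1.535, 0.897, 1.069, 2.079, 0.236, -0.729, -0.925, -0.142),
    y = c(-0.156, 0.996, 0.331, -0.771, 0.270, -0.251, -0.564, 0.859, 0.895, 0.398, -0.545, -0.047, 0.817, 1.044, 0.346, 0.196, 0.869, -0.603, -1.249, -1.144, -0.368),
    z = c(-4.636, -4.255, -5.665, -3.320, -2.744, -1.482, -0.458, -0.835, -1.418, 0.640, 0.797, 1.852, 1.689, 2.835, 3.805, 5.191, 5.856, 5.850, 5.224, 3.927, 3.184)),
  DC = list(
    atom = c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'", "C3'", "O3'", "C2'", "C1'", "N1", "C2", "O2", "N3", "C4", "N4", "C5", "C6"),
    elem = c("P", "O", "O", "O", "C", "C", "O", "C", "O", "C", "C", "N", "C", "O", "N", "C", "N", "C", "C"),
    x = c(0.987, 1.802, -0.119, 0.255, -0.571, -1.300, -0.363, -2.206, -3.488, -2.322, -1.106, -0.267, 0.270, 0.052, 1.037, 1.291, 2.085, 0.746, -0.035),
    y = c(-0.017, 1.099, 0.560, -0.772, 0.196, -0.459, -0.863, 0.569, 0.649, -0.040, -0.981, -0.584, 0.648, 1.424, 1.035, 0.212, 0.622, -1.088, -1.465),
    z = c(-3.894, -3.365, -4.910, -2.674, -2.027, -0.852, 0.171, -0.129, -0.756, 1.288, 1.395, 2.528, 2.563, 1.647, 3.581, 4.589, 5.635, 4.580, 3.541)),
  DT = list(
    atom = c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'", "C3'", "O3'", "C2'", "C1'", "N1", "C2", "O2", "N3", "C4", "O4", "C5", "C7", "C6"),
    elem = c("P", "O", "O", "O", "C", "C", "O", "C", "O", "C", "C", "N", "C", "O", "N", "C", "O", "C", "C", "C"),
    x = c(-3.968, -4.406, -4.901, -2.493, -2.005, -0.611, 0.247, 0.008, 0.965, 0.710, 1.157, 1.164, 2.333, 3.410, 2.194, 1.047, 0.995, -0.143, -1.420, -0.013),
    y = c(-1.665, -2.599, -0.360, -1.028, -0.136, 0.328, -0.829, 1.286, 2.121, 0.360, -0.778, -2.047, -2.544, -1.945, -3.793, -4.570, -5.663, -3.980, -4.757, -2.784),
    z = c(3.118, 4.208, 2.920, 3.315, 2.327, 2.728, 2.764, 1.720, 2.368, 0.754, 1.657, 0.989, 0.374, 0.363, -0.240, -0.300, -0.857, 0.369, 0.347, 0.958))
)

# ring atoms defining the base plane / centroid per nucleotide
BASE_RING_ATOMS <- list(
  DG = c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4"),
  DA = c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4"),
  DC = c("N1", "C2", "N3", "C4", "C5", "C6"),
  DT = c("N1", "C2", "N3", "C4", "C5", "C6")
)
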