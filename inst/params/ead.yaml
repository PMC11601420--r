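# Calibrated cell parameters, REDUCED Ca-induced inactivation (aca = 0.09):
# the EAD regime.  Identical to default.yaml except for aca.
# Units: mV, ms, uA/uF, uM unless noted.  Values marked [cal] were fixed by
# the package calibration procedure against the printed single-cell targets
# (mean APD90 ~ 237 ms, sigma ~ 6.3 ms, cv ~ 2.7% at CL = 500 ms with
# Nb = 4000 junctional clusters, and an EAD onset near CL ~ 500 ms when
# aca is reduced to 0.09).

# --- ionic conductances (rabbit ventricular current set) ---
gna: 10.0        # fast Na conductance, mS/uF [cal]
gtof: 0.11       # transient outward
gkr: 0.095       # rapid delayed rectifier [cal]
gks: 0.24        # slow delayed rectifier [cal]
gk1: 1.08        # inward rectifier [cal]
gnak: 1.5        # Na/K pump scale
gnaca: 38400.0   # Na/Ca exchanger scale [cal]; the exchanger carries the
                 # spark-noise coupling into voltage
pca: 43.2        # L-type current scale [cal]

# --- ionic milieu (mM) ---
nao: 136.0
ko: 5.4
ki: 140.0
cao: 1.8
rtf: 26.54       # RT/F, mV

# --- L-type Ca channel Markov scheme ---
a24o: 0.00131    # Ca-independent inactivation baseline, 1/ms [cal]
a34o: 0.01
aca: 0.09        # reduced Ca-induced inactivation: EAD regime
cth: 1.0         # Ca-inactivation threshold, uM [cal]
cspark: 100.0    # local Ca seen by spark-on channels, uM
k12: 1.0         # C1<->C2 activation rate scale, 1/ms
v12: -26.0       # C1->C2 midpoint, mV [cal]
s12: 8.0
k23: 1.5         # C2<->O rate scale, 1/ms
v23: -15.0       # C2->O midpoint, mV [cal]
s23: 6.0
r42a: 0.008      # I1->O recovery floor (plateau), 1/ms [cal]
r42b: 0.034      # I1->O recovery amplitude at rest [cal]
v42: 35.0        # recovery midpoint magnitude, mV
s42: 6.0
r43a: 0.0008     # I2->C2 recovery floor
r43b: 0.012
v43: 35.0
s43: 6.0
couple_all: 1    # 1: all corresponding spark-on/off states exchange

# --- Ca spark recruitment ---
alpha0: 0.0925   # recruitment scale, 1/ms [cal]
ksr: 467.2       # SR-load half-saturation of recruitment, uM [cal]
beta_b: 0.03333333333333333   # spark extinction rate = 1/(30 ms)

# --- Ca compartments ---
gb: 0.36         # RyR cluster release conductance, 1/ms [cal]
vup_b: 3.836     # SERCA max rate near J clusters, uM/ms (per SR volume) [cal]
vup_i: 1.5
kup: 0.5         # SERCA half-saturation, uM
tau_c: 3.0       # cytosolic J<->NJ exchange time constant, ms
tau_sr: 33.33    # SR J<->NJ exchange time constant, ms [cal]
vb: 0.35         # relative cytosolic volume near J clusters
vi: 1.0
vsrb: 0.02       # relative SR volume near J clusters
vsri: 0.06
buf_cb: 0.15     # instantaneous buffering factors (free/total)
buf_ci: 0.06
buf_csrb: 1.0
buf_csri: 1.0
jri_on: 0        # NJ release disabled by default
gi: 0.0
cith: 1.0

# --- membrane <-> Ca conversions ---
conv_ica: 0.0503 # uM/ms per uA/uF of L-type current [cal]
conv_ncx: 0.2    # uM/ms per uA/uF of exchanger current (1 Ca per charge)
conv_na: 6.0e-6  # mM/ms per uA/uF for Na bookkeeping
allo_c: 0.3      # NCX allosteric Ca activation, uM
na_dynamic: 0

# --- stimulus / numerics ---
stim_amp: -80.0  # uA/uF
stim_dur: 1.0    # ms
dt_fast: 0.01
dt_slow: 0.1
dvdt_fast: 1.0   # |dV/dt| above which the fast step is used, mV/ms
tauj_scale: 1.0  # scales j-gate recovery time constant
vkr: -33.0       # IKr rectification midpoint, mV
skr: 22.4        # IKr rectification slope, mV
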