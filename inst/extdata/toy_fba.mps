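* Toy flux-balance network: uptake -> A -> B -> biomass, with a
* bypass reaction.  Steady state S v = 0, maximize the biomass flux.
NAME          TOYFBA
OBJSENSE
    MAX
ROWS
 N  OBJ
 E  MET_A
 E  MET_B
COLUMNS
    UPTAKE    MET_A     1.0
    R_AB      MET_A     -1.0
    R_AB      MET_B     1.0
    BYPASS    MET_A     -1.0
    BYPASS    MET_B     0.5
    BIOMASS   MET_B     -1.0
    BIOMASS   OBJ       1.0
RHS
BOUNDS
 UP BND       UPTAKE    10.0
 UP BND       R_AB      8.0
 UP BND       BYPASS    10.0
 UP BND       BIOMASS   100.0
ENDATA
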