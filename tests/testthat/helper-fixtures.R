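# Shared fixture helpers: build the TMFA problem for a generated fixture
# and collect solutions for the second-law audit.

tf_build <- function(fx, config = thermo_config()) {
  th <- assemble_reaction_thermo(fx$network, fx$thermo)
  lum <- build_lumped_reactions(fx$network, th, fx$thermo)
  list(th = th, lum = lum,
       problem = build_tmfa(fx$network, th, lum, config),
       config = config)
}

# A tiny SBML Level 3 (core + fbc) document used by the reader tests.
tf_sbml_fixture <- function(path) {
  writeLines('<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1"
      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2">
  <model id="toy" fbc:strict="true">
    <listOfCompartments><compartment id="c" constant="true"/></listOfCompartments>
    <listOfParameters>
      <parameter id="lb_m5" value="-5" constant="true"/>
      <parameter id="lb_0" value="0" constant="true"/>
      <parameter id="ub_100" value="100" constant="true"/>
    </listOfParameters>
    <listOfSpecies>
      <species id="A" compartment="c" constant="false" boundaryCondition="false" hasOnlySubstanceUnits="false"/>
      <species id="B" compartment="c" constant="false" boundaryCondition="false" hasOnlySubstanceUnits="false"/>
    </listOfSpecies>
    <fbc:listOfGeneProducts>
      <fbc:geneProduct fbc:id="gp1" fbc:label="g1"/>
      <fbc:geneProduct fbc:id="gp2" fbc:label="g2"/>
    </fbc:listOfGeneProducts>
    <listOfReactions>
      <reaction id="EX_A" reversible="true" fast="false" fbc:lowerFluxBound="lb_m5" fbc:upperFluxBound="ub_100">
        <listOfReactants><speciesReference species="A" stoichiometry="1" constant="true"/></listOfReactants>
      </reaction>
      <reaction id="R1" reversible="false" fast="false" fbc:lowerFluxBound="lb_0" fbc:upperFluxBound="ub_100">
        <listOfReactants><speciesReference species="A" stoichiometry="1" constant="true"/></listOfReactants>
        <listOfProducts><speciesReference species="B" stoichiometry="2" constant="true"/></listOfProducts>
        <fbc:geneProductAssociation>
          <fbc:or>
            <fbc:geneProductRef fbc:geneProduct="gp1"/>
            <fbc:geneProductRef fbc:geneProduct="gp2"/>
          </fbc:or>
        </fbc:geneProductAssociation>
      </reaction>
      <reaction id="EX_B" reversible="false" fast="false" fbc:lowerFluxBound="lb_0" fbc:upperFluxBound="ub_100">
        <listOfReactants><speciesReference species="B" stoichiometry="1" constant="true"/></listOfReactants>
      </reaction>
    </listOfReactions>
    <fbc:listOfObjectives fbc:activeObjective="obj1">
      <fbc:objective fbc:id="obj1" fbc:type="maximize">
        <fbc:listOfFluxObjectives>
          <fbc:fluxObjective fbc:reaction="EX_B" fbc:coefficient="1"/>
        </fbc:listOfFluxObjectives>
      </fbc:objective>
    </fbc:listOfObjectives>
  </model>
</sbml>', path)
  path
}
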