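<?xml version="1.0" encoding="UTF-8"?>
<!-- hand-written two-module toy, main file: one helper species joining the
     producer port in TU_X (replacedBy) to the consumer port in pool_X
     (replacedElement) -->
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"
      xmlns:comp="http://www.sbml.org/sbml/level3/version1/comp/version1"
      level="3" version="1" comp:required="true">
  <comp:listOfExternalModelDefinitions>
    <comp:externalModelDefinition comp:id="TU_X_def" comp:source="TU_X.xml"
                                  comp:modelRef="TU_X"/>
    <comp:externalModelDefinition comp:id="pool_X_def" comp:source="pool_X.xml"
                                  comp:modelRef="pool_X"/>
  </comp:listOfExternalModelDefinitions>
  <model id="toy_cell">
    <listOfCompartments>
      <compartment id="nucleus" size="1" constant="true"/>
      <compartment id="cytoplasm" size="1" constant="true"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="mRNA_X" compartment="cytoplasm" initialAmount="0"
               hasOnlySubstanceUnits="true" boundaryCondition="false"
               constant="false">
        <comp:listOfReplacedElements>
          <comp:replacedElement comp:submodelRef="pool_X"
                                comp:portRef="port_mRNA_X"/>
        </comp:listOfReplacedElements>
        <comp:replacedBy comp:submodelRef="TU_X" comp:portRef="port_mRNA_X"/>
      </species>
    </listOfSpecies>
    <comp:listOfSubmodels>
      <comp:submodel comp:id="TU_X" comp:modelRef="TU_X_def"/>
      <comp:submodel comp:id="pool_X" comp:modelRef="pool_X_def"/>
    </comp:listOfSubmodels>
  </model>
</sbml>
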