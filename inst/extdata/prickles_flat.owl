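<?xml version="1.0" encoding="UTF-8"?>
<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#" xmlns:rdfs="http://www.w3.org/2000/01/rdf-schema#" xmlns:owl="http://www.w3.org/2002/07/owl#" xmlns="http://example.org/trait-ontology#" xml:base="http://example.org/trait-ontology">
  <owl:Ontology rdf:about="http://example.org/trait-ontology"/>
  <owl:ObjectProperty rdf:about="#has_distance"/>
  <owl:AnnotationProperty rdf:about="#distance"/>
  <owl:Class rdf:about="#Prickle_quantity">
    <rdfs:label>Prickle quantity</rdfs:label>
  </owl:Class>
  <owl:Class rdf:about="#Few_prickles">
    <rdfs:label>Few prickles</rdfs:label>
    <rdfs:subClassOf rdf:resource="#Prickle_quantity"/>
  </owl:Class>
  <owl:Class rdf:about="#Many_prickles">
    <rdfs:label>Many prickles</rdfs:label>
    <rdfs:subClassOf rdf:resource="#Prickle_quantity"/>
  </owl:Class>
  <owl:Class rdf:about="#Low">
    <rdfs:label>Low</rdfs:label>
    <rdfs:subClassOf rdf:resource="#Few_prickles"/>
  </owl:Class>
  <owl:Class rdf:about="#Medium">
    <rdfs:label>Medium</rdfs:label>
    <rdfs:subClassOf rdf:resource="#Few_prickles"/>
  </owl:Class>
  <owl:Class rdf:about="#High">
    <rdfs:label>High</rdfs:label>
    <rdfs:subClassOf rdf:resource="#Many_prickles"/>
  </owl:Class>
  <owl:Class rdf:about="#Very_high">
    <rdfs:label>Very high</rdfs:label>
    <rdfs:subClassOf rdf:resource="#Many_prickles"/>
  </owl:Class>
  <owl:Axiom>
    <owl:annotatedSource rdf:resource="#Low"/>
    <owl:annotatedProperty rdf:resource="#has_distance"/>
    <owl:annotatedTarget rdf:resource="#Medium"/>
    <distance rdf:datatype="http://www.w3.org/2002/07/owl#real">1</distance>
  </owl:Axiom>
  <owl:Axiom>
    <owl:annotatedSource rdf:resource="#High"/>
    <owl:annotatedProperty rdf:resource="#has_distance"/>
    <owl:annotatedTarget rdf:resource="#Low"/>
    <distance rdf:datatype="http://www.w3.org/2002/07/owl#real">2</distance>
  </owl:Axiom>
  <owl:Axiom>
    <owl:annotatedSource rdf:resource="#Low"/>
    <owl:annotatedProperty rdf:resource="#has_distance"/>
    <owl:annotatedTarget rdf:resource="#Very_high"/>
    <distance rdf:datatype="http://www.w3.org/2002/07/owl#real">3</distance>
  </owl:Axiom>
  <owl:Axiom>
    <owl:annotatedSource rdf:resource="#High"/>
    <owl:annotatedProperty rdf:resource="#has_distance"/>
    <owl:annotatedTarget rdf:resource="#Medium"/>
    <distance rdf:datatype="http://www.w3.org/2002/07/owl#real">1</distance>
  </owl:Axiom>
  <owl:Axiom>
    <owl:annotatedSource rdf:resource="#Medium"/>
    <owl:annotatedProperty rdf:resource="#has_distance"/>
    <owl:annotatedTarget rdf:resource="#Very_high"/>
    <distance rdf:datatype="http://www.w3.org/2002/07/owl#real">2</distance>
  </owl:Axiom>
  <owl:Axiom>
    <owl:annotatedSource rdf:resource="#High"/>
    <owl:annotatedProperty rdf:resource="#has_distance"/>
    <owl:annotatedTarget rdf:resource="#Very_high"/>
    <distance rdf:datatype="http://www.w3.org/2002/07/owl#real">1</distance>
  </owl:Axiom>
</rdf:RDF>
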