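PREFIX rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#>
PREFIX rdfs: <http://www.w3.org/2000/01/rdf-schema#>
PREFIX owl: <http://www.w3.org/2002/07/owl#>
PREFIX xsd: <http://www.w3.org/2001/XMLSchema#>
PREFIX ohd: <http://purl.example.org/ohd-mini/>
PREFIX ex: <http://purl.example.org/ohd-mini/practice/>
# Tooth surfaces and the patients they are part of.  The surface-to-patient
# parthood is inferred by the store's transitive materialization; with a
# non-reasoning engine the property path below walks the chain explicitly.
SELECT ?surface ?patient
WHERE {
  ?patient rdf:type ohd:human_dental_patient .
  ?surface rdf:type/rdfs:subClassOf* ohd:surface_enamel_of_tooth .
  ?surface ohd:is_part_of+ ?patient .
}
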