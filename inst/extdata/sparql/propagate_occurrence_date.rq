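PREFIX rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#>
PREFIX rdfs: <http://www.w3.org/2000/01/rdf-schema#>
PREFIX owl: <http://www.w3.org/2002/07/owl#>
PREFIX xsd: <http://www.w3.org/2001/XMLSchema#>
PREFIX ohd: <http://purl.example.org/ohd-mini/>
PREFIX ex: <http://purl.example.org/ohd-mini/practice/>
# Copy the visit's occurrence date onto the procedures that are parts of the
# visit (OWL 2 lacks data-property chains, so this is asserted by update).
INSERT {
  ?part ohd:occurrence_date ?date .
}
WHERE {
  ?part ohd:is_part_of ?whole .
  ?whole ohd:occurrence_date ?date .
  FILTER NOT EXISTS { ?part ohd:occurrence_date ?any }
}
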