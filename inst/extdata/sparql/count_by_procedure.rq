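PREFIX rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#>
PREFIX rdfs: <http://www.w3.org/2000/01/rdf-schema#>
PREFIX owl: <http://www.w3.org/2002/07/owl#>
PREFIX xsd: <http://www.w3.org/2001/XMLSchema#>
PREFIX ohd: <http://purl.example.org/ohd-mini/>
PREFIX ex: <http://purl.example.org/ohd-mini/practice/>
# Count translated procedure instances per asserted procedure class.
SELECT ?procedure_name (COUNT(DISTINCT ?procedure) AS ?total)
WHERE {
  ?procedure rdf:type ?class .
  ?class rdfs:subClassOf* ohd:dental_procedure .
  ?class rdfs:label ?procedure_name .
}
GROUP BY ?procedure_name
ORDER BY DESC(?total)
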