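PREFIX rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#>
PREFIX rdfs: <http://www.w3.org/2000/01/rdf-schema#>
PREFIX owl: <http://www.w3.org/2002/07/owl#>
PREFIX xsd: <http://www.w3.org/2001/XMLSchema#>
PREFIX ohd: <http://purl.example.org/ohd-mini/>
PREFIX ex: <http://purl.example.org/ohd-mini/practice/>
# Restoration procedures using resin, broken down by procedure type.
SELECT ?procedure_name (COUNT(DISTINCT ?procedure) AS ?total)
WHERE {
  ?material rdf:type/rdfs:subClassOf* ohd:resin_dental_restoration_material .
  ?procedure ohd:has_specified_input ?material .
  ?procedure rdf:type ?class .
  ?class rdfs:label ?procedure_name .
}
GROUP BY ?procedure_name
ORDER BY DESC(?total)
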