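PREFIX rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#>
PREFIX rdfs: <http://www.w3.org/2000/01/rdf-schema#>
PREFIX owl: <http://www.w3.org/2002/07/owl#>
PREFIX xsd: <http://www.w3.org/2001/XMLSchema#>
PREFIX ohd: <http://purl.example.org/ohd-mini/>
PREFIX ex: <http://purl.example.org/ohd-mini/practice/>
# Total number of crown restoration procedures, using the class hierarchy
# instead of enumerating billing codes.
SELECT (COUNT(DISTINCT ?procedure) AS ?total_crowns)
WHERE {
  ?procedure rdf:type/rdfs:subClassOf* ohd:crown_restoration_procedure .
}
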